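Package: dddthresh
Title: Distance-Dependent Distribution Thresholding for Tractography Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Thresholds probabilistic-tractography connectivity matrices with
    empirical, distance-dependent null distributions. Connection scores between
    spherical regions of interest are pooled into inter-regional distance bins,
    a Monte-Carlo sampling distribution is resampled per bin, and per-bin
    thresholds at user-chosen alpha levels are applied to individual or
    group-average matrices, yielding nested networks across alpha levels.
    Includes streamline endpoint assignment with a radial search zone, Euclidean
    and minimum-streamline-length distance measures, a uniform percentile
    baseline, and a synthetic cohort generator with planted short- and
    long-range bundles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
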