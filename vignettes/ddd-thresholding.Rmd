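---
title: "Distance-dependent thresholding of tractography connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-dependent thresholding of tractography connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dddthresh)
```

## The problem

Probabilistic tractography samples streamline trajectories from
fibre-orientation distributions, so every seed region emits streamlines to
many targets, most of them spurious, and the probability that a streamline
survives all the way to a distant target decays with path length. A single
uniform cutoff on connection strength therefore cannot be right at both ends
of the distance axis: a cutoff strict enough to suppress short-range false
positives deletes genuine long-range bundles, and a cutoff lenient enough to
keep the long bundles floods the short range with noise.

`dddthresh` implements distance-dependent thresholding: the null
distribution of connection scores is estimated *locally in distance*, and
each connection is tested against the null of its own distance stratum.

## Connection scores

Regions of interest (ROIs) are spheres (default radius 8 mm) in a common
millimetre space. Only streamline *termini* count: a terminus is captured by
an ROI when it lies within a radial search distance (default 4 mm) of the
sphere surface, i.e. centre distance at most radius + search; streamlines
passing through an ROI are ignored. For ROIs $A$ and $B$, the directed score
is

$$s_{A \to B} = \frac{\#\{\text{streamlines with one terminus in } A
\text{ and the other in } B\}}{\#\{\text{streamlines with at least one
terminus in } A\}},$$

and the reported score is $s_{AB} = \tfrac12 (s_{A\to B} + s_{B\to A})$, a
proportion in $[0,1]$. The denominator is our design choice — the field
phrase "proportion of streamlines emerging from the seed" does not pin it
down — because it makes the score a conditional endpoint frequency that is
comparable across subjects regardless of tractogram size. A streamline with
both termini in the same ROI enters that ROI's denominator once and no
pair's numerator. When a terminus is captured by several ROIs the nearest
centre wins, with exact ties broken by lexicographic id; this only matters
for overlapping or nearly touching spheres, which the ROI constructor flags.

## Distance measures

Two measures are supported, both rounded to integer millimetres with a fixed
half-away-from-zero rule (16.5 → 17) so matrices are bit-reproducible:

* **Euclidean** — centre-to-centre distance.
* **Streamline** — per subject, the minimum arc length over streamlines
  connecting the pair; averaged across subjects, where subjects with no
  connecting streamline are dropped from the average (a pair missing in
  every subject has no streamline distance). We read the missing-data rule
  as *discard the subject's value, keep the pair*, which maximises usable
  pairs; discarding whole pairs would be the conservative alternative.

Streamline distances are never shorter than the terminus separation (arc
length bounds the chord), track Euclidean distances closely in rank, and
reflect actual anatomy at the cost of requiring tractograms.

## Distance bins

Integer distances are pooled into contiguous bins, each holding at least
`min_samples` ROI-pair samples (conventional choices: 1000 for Euclidean,
1500 for streamline distances, which on a hemisphere-covering grid of 230
ROIs yield 26 bins). The binning is a greedy left-to-right scan over the
sorted unique distances: accumulate consecutive distances until the running
count reaches the minimum, close the bin, continue. `min_samples` is the
primary parameter and the bin count is emergent — equal-width bins would
leave the long-distance tail under-sampled. Two boundary rules are ours: a
terminal shortfall is merged into the previous bin (an under-powered final
null would otherwise produce unstable thresholds at exactly the distances
the method exists for), and when a matrix being thresholded contains a
distance never seen during binning, `locate_bin()` clamps below/above the
binned range and sends in-range gaps to the nearest bin boundary, lower bin
on ties.

## Monte-Carlo null and thresholds

For each bin, `fit_ddd()` draws `n_draws` (default 100,000) scores with
replacement from the bin's candidate scores, giving an empirical sampling
distribution, and extracts a threshold per alpha level (defaults 0.1, 0.2,
0.3): the smallest draw value $t$ such that the fraction of draws strictly
above $t$ is at most $\alpha$ (a nearest-rank-lower quantile). With the
heavy ties at zero typical of long-distance bins this realises "$\alpha$ of
the distribution lies above the threshold" as closely as a finite sample
can. Resampling is the canonical path for fidelity to the procedure as
practised; on a fixed candidate set it agrees with the analytic candidate
quantile to within the adjacent order statistics, which the test suite
checks across seeds.

Reproducibility choices: each bin draws from its own seed, derived as
`master_seed + bin_index`, so thresholds for a bin do not depend on how many
bins precede it; fitting twice with the same seed yields byte-identical
serialized models.

An edge's tier is the smallest alpha whose threshold its score *strictly*
exceeds. Strictness is deliberate: in a bin whose candidates are nearly all
zero the threshold is 0 at every alpha, and a zero-score edge must not be
declared significant. Because thresholds are non-increasing in alpha, tiers
nest: the alpha = 0.1 network is a subgraph of the 0.2 network, which is a
subgraph of the 0.3 network. Thresholds are per-bin step functions of
distance, not interpolated, matching how the per-bin nulls are built.
Group-level use applies the model to the *unthresholded* average matrix
(individual matrices need not be sparse); individual-level use is the same
call on a single-subject matrix.

## The uniform percentile baseline

`percentile_threshold()` is the distance-blind comparator: one cutoff at the
$P$-th nearest-rank percentile of all off-diagonal scores, strict survival.
`match_count_threshold()` keeps the $k$ strongest edges — the fair
comparison against a distance-dependent network with $k$ survivors, since it
removes the choice of $P$ from the contrast.

## The synthetic cohort generator

Real nulls here are empirical; no generative model is claimed by the method
itself. The generator exists to *emulate the phenomenology the method
assumes* so that every stage can be tested end to end with known ground
truth:

* **Null pairs** at distance $d$: zero with probability
  $\pi_0(d) = 0.9\,(1 - e^{-d/60})$ (zero inflation growing with distance),
  otherwise $|N(0,\ \sigma_0 e^{-d/\lambda})|$ — right-skewed, decaying,
  with $\sigma_0 = 0.5$ and $\lambda = 40$ mm.
* **Planted bundles**: lognormal with median $m\,e^{-d/(2\lambda)}$ and
  log-sd 0.4; two classes, strong short-range ($m = 0.8$, $d <$ 40 mm) and
  weak-but-real long-range ($m = 0.125$, $d \ge$ 80 mm), 20 of each by
  default.
* **Geometry**: 60 ROIs of radius 8 mm placed uniformly in a
  150 × 120 × 100 mm box with minimum centre separation of one diameter;
  30 subjects.

The long-bundle median was set so that planted long-range edges sit clearly
above their own distance bin's alpha = 0.1 threshold yet below a uniform
cutoff matched to the same network density — the regime in which uniform
thresholding produces long-range false negatives and distance-dependent
thresholding does not. That contrast is the package's method-level
experiment (`recovery_experiment()`): with the defaults, distance-dependent
thresholding recovers essentially all planted long bundles while the
count-matched uniform cutoff recovers almost none, across seeded
replicates.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring pairs, SIFT-style streamline weighting, subject-level
registration error, U-fibre geometry, or any dependence between edges —
scores are drawn independently per pair given distance. Passing tests on
synthetic cohorts therefore demonstrate correctness of the procedure and
its distance logic, not performance on any particular acquisition.

There is also a small streamline-level generator
(`simulate_tractogram()`) emitting jittered polylines between requested ROI
pairs (arc length ≥ chord by construction) plus background streamlines
placed away from all ROIs; it exercises endpoint assignment, TCK/text IO and
the streamline-distance path on controlled instances.

## Problem sizes and numerical conventions

The test suite and the bundled analysis script run at desk scale, a package
choice keeping every experiment deterministic and quick: cohorts of 30
subjects × 60 ROIs (1770 pairs, `min_samples` 150 giving ~11 bins), 100,000
draws per bin, 20 replicates for the recovery contrast, and 100 subject
matrices for the nesting sweep. Quantities that are ratios of small counts
(connection scores) are kept as exact binary fractions where possible;
distances are integers by construction; JSON serialization writes full
precision so that byte-identity across reruns is meaningful.

## Known limitations

* Thresholds are data-set-specific: a model fitted on one tracking
  configuration does not transfer to another; only the alpha level does.
* No multiple-comparison correction across edges is applied or claimed —
  alpha is a per-bin distribution fraction, not a familywise error rate.
* The greedy binning is order-dependent by design (contiguous in distance);
  it does not optimise equal mass.
* `restrict_to_interface()` tests voxel centres against the sphere, without
  partial-volume interpolation.
* Overlapping ROIs make capture-zone assignment tie-break-dependent; the
  constructor warns but does not forbid them.
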