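# dddthresh

Distance-dependent thresholding for probabilistic-tractography connectomes.

## The problem

Probabilistic tractography propagates streamlines along directions sampled
from fibre-orientation distributions, so it reaches everything a fibre
*might* reach: connectivity matrices are dense with false positives at short
range, while the sampling attrition over long paths suppresses genuine
long-range bundles. Any single uniform cutoff trades one failure mode for
the other. `dddthresh` is for researchers building structural brain networks
from probabilistic tracking who want thresholds that are (a) statistically
interpretable and (b) local in distance, applicable to both individual and
group-average matrices.

## The method

Connection scores between spherical ROIs are conditional endpoint
frequencies: for ROIs A and B,

    s(A→B) = #{streamlines with termini in A and B} / #{streamlines touching A}
    s(AB)  = mean(s(A→B), s(B→A))            — a proportion in [0, 1],

with termini captured within a radial search distance (default 4 mm) of the
sphere surface. All ROI-pair scores are pooled into contiguous integer-mm
distance bins, each holding at least `min_samples` pairs. Per bin, a
Monte-Carlo sampling distribution is drawn with replacement (default 100,000
draws) from the bin's scores, and the threshold at level α is the smallest
value with at most a fraction α of the distribution strictly above it.
Applied to a matrix, each edge is tested against the threshold of *its own
distance bin*; the surviving networks at α = 0.1, 0.2, 0.3 are nested.
A uniform-percentile baseline (`percentile_threshold()`, and a
count-matched variant `match_count_threshold()`) provides the distance-blind
comparison.

## Worked example

Simulate a 30-subject, 60-ROI cohort with planted short- and long-range
bundles, fit the distance-dependent nulls on the group average, and compare
long-range bundle recovery against a count-matched uniform cutoff:

```r
library(dddthresh)

sim <- simulate_cohort(generator_config(seed = 7))
avg <- group_average(sim$matrices)
ut  <- which(upper.tri(avg), arr.ind = TRUE)
pair_scores <- data.frame(distance = sim$distances[ut], score = avg[ut])

binning <- build_bins(pair_scores$distance, min_samples = 150)
model   <- fit_ddd(binning, pair_scores, alphas = c(0.1, 0.2, 0.3),
                   n_draws = 1e5, seed = 7)
model
#> <ddd_model> 11 bins (euclidean), alphas {0.1, 0.2, 0.3}, 100000 draws/bin, seed 7
#>  lo hi n_samples alpha_0.1 alpha_0.2 alpha_0.3
#>  16 38       159   0.54190   0.20170   0.16150
#>  39 50       161   0.09600   0.08417   0.07645
#>  51 59       173   0.06511   0.05624   0.05095
#>  60 68       152   0.04690   0.04261   0.03770
#>  ...
```

Thresholds fall steeply with distance (0.54 at 16–38 mm down to ~0.016 at
92–99 mm) and with alpha — short-range connections must clear a much higher
bar than long-range ones, which is the point of the method.

```r
net <- apply_ddd(model, avg, sim$distances)
net
#> <thresholded_network> 60 ROIs, 1770 edges
#> surviving edges: alpha 0.1: 173; alpha 0.2: 348; alpha 0.3: 523

base <- match_count_threshold(avg, nrow(surviving_edges(net, 0.1)))
ddd_rec  <- evaluate_recovery(sim$truth, net,  sim$distances, alpha = 0.1)
base_rec <- evaluate_recovery(sim$truth, base, sim$distances)
cat(sprintf("long-range sensitivity: DDD %.2f vs uniform %.2f\n",
            ddd_rec$sensitivity_long, base_rec$sensitivity_long))
#> long-range sensitivity: DDD 1.00 vs uniform 0.00
```

The α = 0.1 network is a strict subset of the α = 0.2 and 0.3 networks, and
at matched network density the distance-dependent thresholds recover all 20
planted long-range bundles while the uniform cutoff recovers none — the
long-range false-negative failure mode of uniform thresholding, made
explicit.

A packaged 13-ROI language-network distance matrix
(`language_distance_fixture()`) is used in the examples and tests; its
off-diagonal extremes are 101 mm (IFG_Tri–pFG) and 16 mm (mFG–pFG).

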