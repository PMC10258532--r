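test_that("threshold_at_alpha matches a brute-force scan of candidates", {
  expect_equal(threshold_at_alpha(rep(0, 50), 0.1), 0)
  expect_equal(threshold_at_alpha(1:100, 0.1), 90)
  expect_equal(threshold_at_alpha(c(rep(0, 70), rep(1, 30)), 0.3), 0)
  set.seed(31)
  for (i in 1:20) {
    draws <- sample(make_tied_candidates(300, denom = 40), 120)
    for (a in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
      expect_equal(threshold_at_alpha(draws, a), oracle_threshold(draws, a),
                   info = sprintf("case %d alpha %g", i, a))
    }
  }
  expect_error(threshold_at_alpha(1:10, 0), "in \\(0, 1\\)")
})

test_that("resampling draws uniformly with replacement, seed-deterministic", {
  const <- fit_sampling_distribution(0.5, n_draws = 1000, rng_seed = 3)
  expect_true(all(const$draws == 0.5))

  # binomial oracle: equal-count {0,1} candidates give about half ones
  sd1 <- fit_sampling_distribution(c(0, 1), n_draws = 1e5, rng_seed = 5)
  p_hat <- mean(sd1$draws)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 1e5))
  # every draw is an element of the candidate multiset
  expect_true(all(sd1$draws %in% c(0, 1)))

  sd2 <- fit_sampling_distribution(c(0, 1), n_draws = 1e5, rng_seed = 5)
  expect_identical(sd1$draws, sd2$draws)
  expect_error(fit_sampling_distribution(numeric(0), 100, 1), "empty")
})

test_that("per-bin thresholds are non-increasing in alpha", {
  scores <- make_tied_candidates(4000)
  dists <- rep(10:49, each = 100)
  binning <- build_bins(dists, min_samples = 500)
  model <- fit_ddd(binning, data.frame(distance = dists, score = scores),
                   alphas = c(0.05, 0.1, 0.2, 0.3, 0.5), n_draws = 2e4,
                   seed = 8)
  for (i in seq_len(nrow(model$thresholds))) {
    expect_true(all(diff(model$thresholds[i, ]) <= 0))
  }
})

test_that("stochastically ordered bins give ordered thresholds", {
  # bin 2 candidates are bin 1 candidates scaled by 0.5: every quantile halves
  base <- make_tied_candidates(1000, zero_frac = 0.2)
  pair_scores <- data.frame(
    distance = rep(c(10L, 20L), each = 1000),
    score = c(base, base * 0.5)
  )
  binning <- build_bins(pair_scores$distance, min_samples = 1000)
  expect_equal(nrow(binning$bins), 2)
  model <- fit_ddd(binning, pair_scores, n_draws = 5e4, seed = 2)
  for (j in seq_along(model$alphas)) {
    expect_lte(model$thresholds[2, j], model$thresholds[1, j])
  }

  # identical candidate sets with per-bin seeds still give near-identical
  # thresholds; with heavy ties the resampled quantile is exactly equal
  same <- data.frame(distance = rep(c(10L, 20L), each = 1000),
                     score = rep(base, 2))
  m2 <- fit_ddd(binning, same, n_draws = 5e4, seed = 2)
  expect_equal(m2$thresholds[1, ], m2$thresholds[2, ], tolerance = 0.02)
})

test_that("model fitting is deterministic given the master seed", {
  scores <- make_tied_candidates(2000)
  dists <- rep(c(10L, 30L), each = 1000)
  binning <- build_bins(dists, min_samples = 800)
  f <- function() fit_ddd(binning, data.frame(distance = dists,
                                              score = scores),
                          n_draws = 1e4, seed = 77)
  m1 <- f(); m2 <- f()
  expect_identical(m1$thresholds, m2$thresholds)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ddd_model(m1, p1); write_ddd_model(m2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # and the JSON round-trips into a working model
  m3 <- read_ddd_model(p1)
  expect_equal(m3$thresholds, m1$thresholds, ignore_attr = FALSE)
  expect_identical(m3$binning$bins, binning$bins)
})

test_that("applying the model yields nested tiers routed by distance", {
  # two bins with very different score levels
  pair_scores <- data.frame(
    distance = rep(c(10L, 50L), each = 500),
    score = c(seq(0.5, 1, length.out = 500), seq(0, 0.1, length.out = 500))
  )
  binning <- build_bins(pair_scores$distance, min_samples = 500)
  model <- fit_ddd(binning, pair_scores, n_draws = 2e4, seed = 4)

  ids <- c("a", "b", "c")
  d <- matrix(c(0L, 10L, 50L, 10L, 0L, 50L, 50L, 50L, 0L), 3,
              dimnames = list(ids, ids))
  class(d) <- c("ddd_distance_matrix", class(d))
  attr(d, "measure") <- "euclidean"

  # equal scores, different bins: tier can differ (0.095 clears the long-bin
  # alpha = 0.1 threshold but not even the short-bin alpha = 0.3 one)
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m["a", "b"] <- m["b", "a"] <- 0.095
  m["a", "c"] <- m["c", "a"] <- 0.095
  net <- apply_ddd(model, as_connectivity_matrix(m), d)
  e <- net$edges
  tier_ab <- e$tier[e$roi_a == "a" & e$roi_b == "b"]
  tier_ac <- e$tier[e$roi_a == "a" & e$roi_b == "c"]
  expect_true(is.na(tier_ab))
  expect_equal(tier_ac, 0.1)

  # all-zero matrix: nothing survives under strict exceedance
  z <- as_connectivity_matrix(matrix(0, 3, 3, dimnames = list(ids, ids)))
  nz <- apply_ddd(model, z, d)
  expect_true(all(is.na(nz$edges$tier)))

  # measure mismatch is rejected
  ds <- d; attr(ds, "measure") <- "streamline"
  expect_error(apply_ddd(model, z, ds), "measure")
})

test_that("tier nesting holds on random synthetic matrices", {
  cfg <- generator_config(n_subjects = 3, n_rois = 20, n_short = 4,
                          n_long = 4, seed = 12)
  sim <- simulate_cohort(cfg)
  ut <- which(upper.tri(sim$distances), arr.ind = TRUE)
  avg <- group_average(sim$matrices)
  pair_scores <- data.frame(distance = sim$distances[ut], score = avg[ut])
  binning <- build_bins(pair_scores$distance, min_samples = 40)
  model <- fit_ddd(binning, pair_scores, n_draws = 1e4, seed = 12)
  for (s in 1:20) {
    net <- apply_ddd(model, sim$matrices[[(s - 1) %% 3 + 1]], sim$distances)
    e10 <- surviving_edges(net, 0.1)
    e20 <- surviving_edges(net, 0.2)
    e30 <- surviving_edges(net, 0.3)
    key <- function(e) paste(e$roi_a, e$roi_b)
    expect_true(all(key(e10) %in% key(e20)))
    expect_true(all(key(e20) %in% key(e30)))
  }
})

test_that("group averaging is the entrywise mean and respects ordering", {
  ids <- c("a", "b")
  mk <- function(v) as_connectivity_matrix(
    matrix(c(0, v, v, 0), 2, dimnames = list(ids, ids)))
  expect_equal(group_average(list(mk(0.4)))[1, 2], 0.4)
  avg <- group_average(list(mk(0), mk(0.4)))
  expect_equal(avg[1, 2], 0.2)
  expect_equal(attr(avg, "n_subjects"), 2L)

  swapped <- as_connectivity_matrix(
    matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(rev(ids), rev(ids))))
  expect_error(group_average(list(mk(0.1), swapped)), "orderings")

  # mean commutes with a common row/column permutation
  ids3 <- c("a", "b", "c")
  set.seed(2)
  mats <- lapply(1:3, function(i) {
    m <- matrix(0, 3, 3, dimnames = list(ids3, ids3))
    m[upper.tri(m)] <- runif(3)
    as_connectivity_matrix(m + t(m))
  })
  perm <- c(3, 1, 2)
  mats_p <- lapply(mats, function(m) {
    y <- unclass(m)[perm, perm]
    as_connectivity_matrix(y)
  })
  a1 <- group_average(mats)
  a2 <- group_average(mats_p)
  expect_equal(unclass(a2)[ids3, ids3], unclass(a1)[ids3, ids3],
               ignore_attr = TRUE)
})

test_that("percentile baseline uses nearest-rank cutoffs with strict survival", {
  ids <- sprintf("r%02d", 1:15)  # 105 pairs
  m <- matrix(0, 15, 15, dimnames = list(ids, ids))
  m[upper.tri(m)] <- (1:105) / 200
  mat <- as_connectivity_matrix(m + t(m))
  # brute-force oracle on 1..105 scaled: P = 0.4 -> rank ceil(42) = 42,
  # survivors are the 63 larger scores
  net <- percentile_threshold(mat, 0.4)
  expect_equal(sum(net$edges$survives), 63)
  expect_equal(net$cutoff, 42 / 200)

  # nesting across percentiles: stricter cutoffs keep subsets
  surv <- lapply(c(0.05, 0.1, 0.2, 0.4), function(p)
    with(percentile_threshold(mat, p)$edges,
         paste(roi_a, roi_b)[survives]))
  for (i in 1:3) expect_true(all(surv[[i + 1]] %in% surv[[i]]))

  # near-zero percentile keeps every positive edge
  expect_equal(sum(percentile_threshold(mat, 1e-6)$edges$survives), 104)
})

test_that("count-matched uniform baseline keeps exactly k top edges", {
  ids <- sprintf("r%02d", 1:10)
  set.seed(9)
  m <- matrix(0, 10, 10, dimnames = list(ids, ids))
  m[upper.tri(m)] <- round(runif(45), 2)  # ties likely
  mat <- as_connectivity_matrix(m + t(m))
  for (k in c(0, 7, 45)) {
    net <- match_count_threshold(mat, k)
    expect_equal(sum(net$edges$survives), k)
    if (k > 0) {
      kept <- net$edges$score[net$edges$survives]
      dropped <- net$edges$score[!net$edges$survives]
      if (length(dropped)) expect_gte(min(kept), max(dropped))
    }
  }
  expect_error(match_count_threshold(mat, 46), "out of range")
})
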