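# run code under a temporary RNG state so package functions do not clobber
# the caller's random stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Monte-Carlo sampling distribution for one distance bin
#'
#' Draws `n_draws` scores i.i.d. with replacement from the bin's candidate
#' score multiset. The draw sequence is a deterministic function of
#' `rng_seed`.
#'
#' @param scores Non-empty numeric vector of candidate connection scores.
#' @param n_draws Number of draws (>= 1); 100,000 is the conventional default.
#' @param rng_seed Integer seed for this bin's draws.
#' @param bin_index Bin index recorded for bookkeeping.
#' @return A list of class `sampling_distribution`: `draws`, `n_draws`,
#'   `rng_seed`, `bin_index`, `n_candidates`.
#' @export
fit_sampling_distribution <- function(scores, n_draws = 1e5, rng_seed = 1,
                                      bin_index = NA_integer_) {
  if (length(scores) < 1) {
    stop("empty candidate set for bin ", bin_index,
         "; rebuild or merge the bin", call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  draws <- with_seed(rng_seed,
                     scores[sample.int(length(scores), n_draws, replace = TRUE)])
  structure(list(draws = draws, n_draws = as.integer(n_draws),
                 rng_seed = as.integer(rng_seed),
                 bin_index = as.integer(bin_index),
                 n_candidates = length(scores)),
            class = "sampling_distribution")
}

#' Threshold at a given alpha level
#'
#' Returns the smallest draw value `t` such that the fraction of the
#' distribution strictly greater than `t` is at most `alpha` — i.e. the
#' empirical (1 - alpha) quantile under a nearest-rank-lower convention. With
#' heavy ties (e.g. a large atom at zero in long-distance bins) this reads
#' "alpha of the sampling distribution lies above the threshold" as closely as
#' a finite sample allows.
#'
#' @param dist A [fit_sampling_distribution()] result, or a bare numeric
#'   vector of draws.
#' @param alpha Fraction in (0, 1); the proportion of the distribution allowed
#'   above the threshold.
#' @return The threshold score.
#' @examples
#' threshold_at_alpha(1:100, alpha = 0.1) # 90
#' @export
threshold_at_alpha <- function(dist, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  draws <- if (inherits(dist, "sampling_distribution")) dist$draws else dist
  n <- length(draws)
  sorted <- sort(draws)
  k <- floor(alpha * n + 1e-9)  # allowed count strictly above
  sorted[n - k]
}

#' Fit a distance-dependent distribution model
#'
#' Builds one Monte-Carlo sampling distribution per distance bin from the
#' candidate pair scores and extracts thresholds at each alpha level. Each
#' bin's RNG seed is derived as `seed + bin_index`, so results do not depend
#' on how many bins precede a given bin.
#'
#' @param binning A [build_bins()] result.
#' @param pair_scores Data frame with columns `distance` (integer mm) and
#'   `score`; one row per candidate ROI-pair sample. Rows with `NA` distance
#'   are dropped.
#' @param alphas Increasing vector of alpha levels in (0, 1).
#' @param n_draws Draws per bin.
#' @param seed Master integer seed.
#' @param keep_draws Keep the raw draws in the returned object (needed only
#'   for diagnostics; thresholds are always kept).
#'
#' @return A list of class `ddd_model`: `binning`, `thresholds` (bins x
#'   alphas matrix), `alphas`, `n_draws`, `seed`, `measure`,
#'   `n_candidates` per bin, and optionally `distributions`.
#' @export
fit_ddd <- function(binning, pair_scores, alphas = c(0.1, 0.2, 0.3),
                    n_draws = 1e5, seed = 1, keep_draws = FALSE) {
  stopifnot(is.data.frame(pair_scores),
            all(c("distance", "score") %in% names(pair_scores)))
  if (is.unsorted(alphas, strictly = TRUE) ||
      any(alphas <= 0) || any(alphas >= 1)) {
    stop("alphas must be strictly increasing, each in (0, 1)", call. = FALSE)
  }
  pair_scores <- pair_scores[!is.na(pair_scores$distance), , drop = FALSE]
  bins <- binning$bins
  nb <- nrow(bins)
  thresholds <- matrix(NA_real_, nb, length(alphas),
                       dimnames = list(NULL, paste0("alpha_", alphas)))
  n_cand <- integer(nb)
  dists <- if (keep_draws) vector("list", nb) else NULL
  for (i in seq_len(nb)) {
    in_bin <- pair_scores$distance >= bins$lo[i] &
      pair_scores$distance <= bins$hi[i]
    cand <- pair_scores$score[in_bin]
    sd_i <- fit_sampling_distribution(cand, n_draws = n_draws,
                                      rng_seed = seed + i, bin_index = i)
    thresholds[i, ] <- vapply(alphas, function(a)
      threshold_at_alpha(sd_i, a), numeric(1))
    n_cand[i] <- length(cand)
    if (keep_draws) dists[[i]] <- sd_i
  }
  structure(list(binning = binning, thresholds = thresholds, alphas = alphas,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 measure = binning$measure, n_candidates = n_cand,
                 distributions = dists),
            class = "ddd_model")
}

#' @export
print.ddd_model <- function(x, ...) {
  cat(sprintf(
    "<ddd_model> %d bins (%s), alphas {%s}, %d draws/bin, seed %d\n",
    nrow(x$binning$bins), x$measure, paste(x$alphas, collapse = ", "),
    x$n_draws, x$seed))
  df <- cbind(x$binning$bins, signif(x$thresholds, 4))
  print(utils::head(df, 8), row.names = FALSE)
  if (nrow(df) > 8) cat("... and", nrow(df) - 8, "more bins\n")
  invisible(x)
}

#' Apply a DDD model to a connectivity matrix
#'
#' Each edge is routed to its distance bin via [locate_bin()] and assigned the
#' smallest alpha level whose threshold its score strictly exceeds (its
#' "tier"). Because per-bin thresholds are non-increasing in alpha, an edge
#' surviving one alpha survives every larger alpha, so the networks at
#' successive alphas are nested. Survival is strict (`score > threshold`), so
#' zero-score edges never survive in all-zero bins. Edges with missing
#' distance are excluded.
#'
#' @param model A [fit_ddd()] result.
#' @param matrix A `connectivity_matrix`.
#' @param distances A `ddd_distance_matrix` with the same ROI ordering and the
#'   same measure as the model.
#' @return A list of class `thresholded_network`: `edges` (data frame `roi_a`,
#'   `roi_b`, `score`, `distance_mm`, `bin`, `tier`; `tier` is the smallest
#'   surviving alpha or `NA`), `alphas`, `roi_ids`.
#' @export
apply_ddd <- function(model, matrix, distances) {
  if (!identical(distance_measure(distances), model$measure)) {
    stop("distance measure '", distance_measure(distances),
         "' does not match model measure '", model$measure, "'",
         call. = FALSE)
  }
  ids <- rownames(matrix)
  if (!identical(ids, rownames(distances))) {
    stop("ROI ordering of matrix and distances differ", call. = FALSE)
  }
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  d <- distances[ut]
  keep <- !is.na(d)
  ut <- ut[keep, , drop = FALSE]; d <- d[keep]
  score <- matrix[ut]
  bin <- locate_bin(model$binning, d)
  tier <- rep(NA_real_, length(score))
  for (j in rev(seq_along(model$alphas))) {
    thr <- model$thresholds[bin, j]
    tier[score > thr] <- model$alphas[j]
  }
  edges <- data.frame(roi_a = ids[ut[, 1]], roi_b = ids[ut[, 2]],
                      score = score, distance_mm = as.integer(d),
                      bin = as.integer(bin), tier = tier,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, alphas = model$alphas, roi_ids = ids),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  n_surv <- vapply(x$alphas, function(a) sum(!is.na(x$edges$tier) &
                                               x$edges$tier <= a), integer(1))
  cat(sprintf("<thresholded_network> %d ROIs, %d edges\n",
              length(x$roi_ids), nrow(x$edges)))
  cat("surviving edges:",
      paste(sprintf("alpha %s: %d", format(x$alphas), n_surv),
            collapse = "; "), "\n")
  invisible(x)
}

#' Edges surviving at a given alpha level
#'
#' @param net A [apply_ddd()] or [percentile_threshold()] result.
#' @param alpha Alpha level (required for tiered networks; ignored for
#'   percentile networks, which carry a single survival flag).
#' @return Data frame of surviving edges.
#' @export
surviving_edges <- function(net, alpha = NULL) {
  e <- net$edges
  if ("tier" %in% names(e)) {
    if (is.null(alpha)) stop("alpha required for a tiered network",
                             call. = FALSE)
    e[!is.na(e$tier) & e$tier <= alpha + 1e-12, , drop = FALSE]
  } else {
    e[e$survives, , drop = FALSE]
  }
}

#' Average connectivity matrices across subjects
#'
#' Entrywise arithmetic mean; zeros are included (an absent connection in one
#' subject pulls the average down rather than being dropped).
#'
#' @param matrices Non-empty list of `connectivity_matrix` objects with
#'   identical ROI orderings.
#' @param group_tag Label recorded on the result.
#' @return A `connectivity_matrix` with `n_subjects` equal to the total number
#'   of subjects averaged.
#' @export
group_average <- function(matrices, group_tag = "group") {
  if (length(matrices) < 1) stop("need >= 1 matrix", call. = FALSE)
  ids <- rownames(matrices[[1]])
  for (m in matrices[-1]) {
    if (!identical(rownames(m), ids)) {
      stop("ROI orderings differ across matrices", call. = FALSE)
    }
  }
  acc <- Reduce(`+`, lapply(matrices, function(m) {
    y <- unclass(m); attributes(y) <- attributes(y)[c("dim", "dimnames")]; y
  }))
  avg <- acc / length(matrices)
  n_tot <- sum(vapply(matrices, function(m)
    attr(m, "n_subjects") %||% 1L, integer(1)))
  as_connectivity_matrix(avg, subject_id = group_tag, n_subjects = n_tot)
}

#' Uniform percentile baseline threshold
#'
#' The distance-blind comparison baseline: the cutoff is the `percentile`-th
#' nearest-rank percentile of the off-diagonal (upper-triangle) scores, and an
#' edge survives when its score strictly exceeds the cutoff. Larger
#' percentiles give stricter networks; survival sets are nested across
#' percentiles.
#'
#' @param matrix A `connectivity_matrix`.
#' @param percentile Fraction in (0, 1), e.g. 0.4 for the 40th percentile.
#' @return A list of class `percentile_network`: `edges` (data frame `roi_a`,
#'   `roi_b`, `score`, `survives`), `cutoff`, `percentile`.
#' @export
percentile_threshold <- function(matrix, percentile) {
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must be in (0, 1)", call. = FALSE)
  }
  ids <- rownames(matrix)
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  score <- matrix[ut]
  sorted <- sort(score)
  rank <- ceiling(percentile * length(sorted))
  cutoff <- sorted[max(rank, 1L)]
  edges <- data.frame(roi_a = ids[ut[, 1]], roi_b = ids[ut[, 2]],
                      score = score, survives = score > cutoff,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, cutoff = cutoff, percentile = percentile),
            class = "percentile_network")
}

#' @export
print.percentile_network <- function(x, ...) {
  cat(sprintf(
    "<percentile_network> cutoff %.4g (P = %g): %d of %d edges survive\n",
    x$cutoff, x$percentile, sum(x$edges$survives), nrow(x$edges)))
  invisible(x)
}

#' Uniform baseline matched to a target surviving-edge count
#'
#' Keeps the `k` strongest off-diagonal edges under a single distance-blind
#' cutoff — the fair comparator for a distance-dependent network with `k`
#' surviving edges. Ties at the cutoff are broken deterministically by ROI id
#' order so exactly `k` edges survive.
#'
#' @param matrix A `connectivity_matrix`.
#' @param k Number of edges to keep (0 <= k <= number of pairs).
#' @return A `percentile_network` whose `edges$survives` marks the top `k`
#'   edges.
#' @export
match_count_threshold <- function(matrix, k) {
  ids <- rownames(matrix)
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  score <- matrix[ut]
  if (k < 0 || k > length(score)) stop("k out of range", call. = FALSE)
  ord <- order(-score, ids[ut[, 1]], ids[ut[, 2]])
  survives <- logical(length(score))
  survives[ord[seq_len(k)]] <- TRUE
  edges <- data.frame(roi_a = ids[ut[, 1]], roi_b = ids[ut[, 2]],
                      score = score, survives = survives,
                      stringsAsFactors = FALSE)
  cutoff <- if (k > 0) score[ord[k]] else Inf
  structure(list(edges = edges, cutoff = cutoff, percentile = NA_real_),
            class = "percentile_network")
}

#' Serialize a DDD model to JSON
#'
#' Writes the binning, the per-bin threshold table per alpha, and the
#' reproducibility metadata (seed, draw count, measure, candidate counts).
#' Raw draws are not serialized; the model is reproducible from the seed.
#' Output is byte-identical across runs with identical inputs and seed.
#'
#' @param model A [fit_ddd()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ddd_model <- function(model, path) {
  thr <- as.data.frame(model$thresholds)
  jsonlite::write_json(list(
    format = "ddd_model",
    measure = model$measure,
    alphas = model$alphas,
    n_draws = model$n_draws,
    seed = model$seed,
    min_samples = model$binning$min_samples,
    terminal_merged = model$binning$terminal_merged,
    under_min = model$binning$under_min,
    bins = cbind(model$binning$bins, n_candidates = model$n_candidates, thr)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a DDD model from JSON
#'
#' @param path File written by [write_ddd_model()].
#' @return A `ddd_model` (without raw draws).
#' @export
read_ddd_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "ddd_model")) stop("not a ddd_model file",
                                              call. = FALSE)
  alphas <- as.numeric(x$alphas)
  thr_cols <- paste0("alpha_", alphas)
  thresholds <- as.matrix(x$bins[, thr_cols, drop = FALSE])
  dimnames(thresholds) <- list(NULL, thr_cols)
  binning <- structure(list(
    bins = data.frame(lo = as.integer(x$bins$lo), hi = as.integer(x$bins$hi),
                      n_samples = as.integer(x$bins$n_samples)),
    measure = x$measure, min_samples = as.integer(x$min_samples),
    terminal_merged = isTRUE(x$terminal_merged),
    under_min = isTRUE(x$under_min)
  ), class = "distance_binning")
  structure(list(binning = binning, thresholds = thresholds, alphas = alphas,
                 n_draws = as.integer(x$n_draws), seed = as.integer(x$seed),
                 measure = x$measure,
                 n_candidates = as.integer(x$bins$n_candidates),
                 distributions = NULL),
            class = "ddd_model")
}
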