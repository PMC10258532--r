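#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure that distance-dependent
#' thresholding assumes: per-pair connection scores that are zero-inflated,
#' right-skewed, and decaying with inter-ROI distance, plus a set of planted
#' "true" bundles — strong short-range edges and weak-but-real long-range
#' edges — whose recovery can be measured against ground truth.
#'
#' Per subject, a non-planted pair at distance `d` scores 0 with probability
#' `pi0(d) = zero_p_max * (1 - exp(-d / zero_d_scale))` (zero inflation
#' increasing with distance) and otherwise `|Normal(0, sigma0 *
#' exp(-d / lambda))|` (a half-normal whose scale decays with distance). A
#' planted pair scores `Lognormal` with median `m * exp(-d / (2 * lambda))`,
#' where `m` is the class median (`median_short` or `median_long`). All scores
#' are clipped to \[0, 1\] and matrices are symmetric with zero diagonal.
#'
#' @param n_subjects Cohort size.
#' @param n_rois Number of spherical ROIs, placed uniformly at random in the
#'   box with a minimum centre separation of `2 * roi_radius`.
#' @param extent_mm Length-3 box extent in mm.
#' @param roi_radius Sphere radius, mm.
#' @param n_short,n_long Number of planted short-range (distance <
#'   `short_max_mm`) and long-range (distance >= `long_min_mm`) bundles.
#' @param short_max_mm,long_min_mm Distance cuts defining the two classes.
#' @param lambda Distance-decay length of the null scale and planted medians,
#'   mm.
#' @param sigma0 Null half-normal scale at distance 0.
#' @param zero_p_max,zero_d_scale Zero-inflation parameters (asymptotic zero
#'   probability and its distance scale, mm).
#' @param median_short,median_long Planted-bundle median scores at distance 0.
#' @param sdlog Lognormal log-scale spread of planted scores.
#' @param seed Master integer seed; everything downstream derives from it.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 30, n_rois = 60,
                             extent_mm = c(150, 120, 100), roi_radius = 8,
                             n_short = 20, n_long = 20,
                             short_max_mm = 40, long_min_mm = 80,
                             lambda = 40, sigma0 = 0.5,
                             zero_p_max = 0.9, zero_d_scale = 60,
                             median_short = 0.8, median_long = 0.125,
                             sdlog = 0.4, seed = 1) {
  stopifnot(lambda > 0, sigma0 >= 0, sdlog >= 0,
            zero_p_max >= 0, zero_p_max <= 1, zero_d_scale > 0,
            n_subjects >= 1, n_rois >= 2, length(extent_mm) == 3)
  structure(list(
    n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
    extent_mm = as.numeric(extent_mm), roi_radius = roi_radius,
    n_short = as.integer(n_short), n_long = as.integer(n_long),
    short_max_mm = short_max_mm, long_min_mm = long_min_mm,
    lambda = lambda, sigma0 = sigma0,
    zero_p_max = zero_p_max, zero_d_scale = zero_d_scale,
    median_short = median_short, median_long = median_long,
    sdlog = sdlog, seed = as.integer(seed)
  ), class = "generator_config")
}

zero_inflation_prob <- function(cfg, d) {
  cfg$zero_p_max * (1 - exp(-d / cfg$zero_d_scale))
}

#' Simulate a synthetic cohort of connectivity matrices
#'
#' Generates an ROI set, per-subject symmetric connectivity matrices under the
#' model described in [generator_config()], and the planted ground truth.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `rois` (an [roi_set()]), `matrices` (list of
#'   `connectivity_matrix`, one per subject), `truth` (data frame `roi_a`,
#'   `roi_b`, `class`, `distance_mm`, `median_score`), `distances`
#'   (Euclidean `ddd_distance_matrix`), and `config`.
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  with_seed(cfg$seed, {
    rois <- random_roi_set(cfg)
    dmat <- distance_matrix(rois)
    truth <- plant_bundles(cfg, dmat)
    ids <- rois$id
    k <- length(ids)
    ut <- which(upper.tri(dmat), arr.ind = TRUE)
    d <- dmat[ut]
    planted_idx <- match(paste(truth$roi_a, truth$roi_b),
                         paste(ids[ut[, 1]], ids[ut[, 2]]))
    meanlog <- rep(NA_real_, length(d))
    meanlog[planted_idx] <- log(truth$median_score)
    p0 <- zero_inflation_prob(cfg, d)
    sigma_d <- cfg$sigma0 * exp(-d / cfg$lambda)

    matrices <- lapply(seq_len(cfg$n_subjects), function(s) {
      score <- numeric(length(d))
      null_sel <- is.na(meanlog)
      nz <- stats::runif(sum(null_sel)) >= p0[null_sel]
      vals <- abs(stats::rnorm(sum(null_sel), 0, sigma_d[null_sel])) * nz
      score[null_sel] <- vals
      np <- sum(!null_sel)
      if (np > 0) {
        score[!null_sel] <- stats::rlnorm(np, meanlog[!null_sel], cfg$sdlog)
      }
      score <- pmin(pmax(score, 0), 1)
      m <- matrix(0, k, k, dimnames = list(ids, ids))
      m[ut] <- score
      m <- m + t(m)
      as_connectivity_matrix(m, subject_id = sprintf("sim%02d", s))
    })
    list(rois = rois, matrices = matrices, truth = truth, distances = dmat,
         config = cfg)
  })
}

# uniform ROI centres in the box with minimum separation 2 * radius
random_roi_set <- function(cfg) {
  centres <- matrix(NA_real_, cfg$n_rois, 3)
  min_sep2 <- (2 * cfg$roi_radius)^2
  placed <- 0
  attempts <- 0
  while (placed < cfg$n_rois) {
    attempts <- attempts + 1
    if (attempts > 10000 * cfg$n_rois) {
      stop("could not place ROIs; box too small for n_rois at this radius",
           call. = FALSE)
    }
    p <- stats::runif(3) * cfg$extent_mm
    if (placed > 0) {
      d2 <- colSums((t(centres[seq_len(placed), , drop = FALSE]) - p)^2)
      if (any(d2 < min_sep2)) next
    }
    placed <- placed + 1
    centres[placed, ] <- p
  }
  roi_set(sprintf("s%03d", seq_len(cfg$n_rois)),
          centres[, 1], centres[, 2], centres[, 3],
          radius = cfg$roi_radius, space_tag = "synthetic")
}

# choose planted pairs from the realized geometry; roi_a < roi_b by id
plant_bundles <- function(cfg, dmat) {
  ids <- rownames(dmat)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[ut]
  pick <- function(sel, n, what) {
    if (sum(sel) < n) {
      stop("only ", sum(sel), " candidate pairs for ", what,
           " bundles (need ", n, "); enlarge the box or relax the cuts",
           call. = FALSE)
    }
    sample(which(sel), n)
  }
  short_i <- pick(d < cfg$short_max_mm, cfg$n_short, "short")
  long_i <- pick(d >= cfg$long_min_mm & !(seq_along(d) %in% short_i),
                 cfg$n_long, "long")
  idx <- c(short_i, long_i)
  cls <- rep(c("short_bundle", "long_bundle"),
             c(cfg$n_short, cfg$n_long))
  med0 <- ifelse(cls == "short_bundle", cfg$median_short, cfg$median_long)
  truth <- data.frame(
    roi_a = ids[ut[idx, 1]], roi_b = ids[ut[idx, 2]],
    class = cls, distance_mm = as.integer(d[idx]),
    median_score = med0 * exp(-d[idx] / (2 * cfg$lambda)),
    stringsAsFactors = FALSE
  )
  truth[order(truth$roi_a, truth$roi_b), , drop = FALSE]
}

#' Simulate a small tractogram with prescribed pair connections
#'
#' Emits, for each requested ROI pair, the requested number of streamlines
#' running from a random point inside the first sphere to a random point
#' inside the second, as jittered polylines (arc length >= straight-line
#' endpoint separation by construction). Optional background streamlines are
#' placed outside the ROI bounding box so they touch no ROI. Exercises the
#' endpoint-assignment and streamline-distance code on controlled instances.
#'
#' @param rois An [roi_set()].
#' @param pair_counts Data frame with columns `roi_a`, `roi_b`, `n`.
#' @param n_background Number of unassigned background streamlines.
#' @param n_points Vertices per streamline polyline.
#' @param jitter_mm Perpendicular jitter amplitude, mm.
#' @param subject_id Subject label.
#' @param seed Integer seed.
#' @return A [tractogram()] in the ROI set's space.
#' @export
simulate_tractogram <- function(rois, pair_counts, n_background = 0,
                                n_points = 12, jitter_mm = 1,
                                subject_id = "sim", seed = 1) {
  stopifnot(all(c("roi_a", "roi_b", "n") %in% names(pair_counts)),
            all(pair_counts$n >= 0))
  with_seed(seed, {
    centres <- roi_centres(rois)
    sl <- list()
    rand_in_sphere <- function(centre, radius) {
      repeat {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) return(centre + radius * p)
      }
    }
    for (r in seq_len(nrow(pair_counts))) {
      a <- pair_counts$roi_a[r]; b <- pair_counts$roi_b[r]
      ra <- rois$radius[match(a, rois$id)]
      rb <- rois$radius[match(b, rois$id)]
      for (q in seq_len(pair_counts$n[r])) {
        p0 <- rand_in_sphere(centres[a, ], ra * 0.9)
        p1 <- rand_in_sphere(centres[b, ], rb * 0.9)
        tt <- seq(0, 1, length.out = n_points)
        path <- outer(1 - tt, p0) + outer(tt, p1)
        if (n_points > 2 && jitter_mm > 0) {
          mid <- 2:(n_points - 1)
          path[mid, ] <- path[mid, ] +
            matrix(stats::runif(length(mid) * 3, -jitter_mm, jitter_mm),
                   ncol = 3)
        }
        sl[[length(sl) + 1]] <- path
      }
    }
    if (n_background > 0) {
      off <- apply(centres, 2, max) + max(rois$radius) + 30
      for (q in seq_len(n_background)) {
        p0 <- off + stats::runif(3, 0, 20)
        p1 <- off + stats::runif(3, 0, 20)
        sl[[length(sl) + 1]] <- rbind(p0, (p0 + p1) / 2, p1)
      }
    }
    tractogram(sl, subject_id = subject_id, space_tag = roi_space(rois))
  })
}

#' Sensitivity and specificity of a thresholded network against ground truth
#'
#' Edges are stratified at `distance_cut` into short (< cut) and long
#' (>= cut). Sensitivity is the fraction of planted edges recovered;
#' specificity the fraction of non-planted pairs correctly rejected.
#'
#' @param truth Ground-truth data frame from [simulate_cohort()] (columns
#'   `roi_a`, `roi_b`; extra columns ignored).
#' @param net A [apply_ddd()] or [percentile_threshold()] network over the
#'   same ROI universe.
#' @param distances A `ddd_distance_matrix` for stratification.
#' @param distance_cut Short/long boundary, mm.
#' @param alpha Alpha level at which to read survivors from a tiered network.
#' @return A list: `sensitivity`, `specificity`, `sensitivity_short`,
#'   `sensitivity_long`, `specificity_short`, `specificity_long`,
#'   `n_surviving`. Strata without eligible edges yield `NaN`.
#' @export
evaluate_recovery <- function(truth, net, distances, distance_cut = 80,
                              alpha = NULL) {
  surv <- surviving_edges(net, alpha)
  all_e <- net$edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  true_keys <- key(truth$roi_a, truth$roi_b)
  all_keys <- key(all_e$roi_a, all_e$roi_b)
  surv_keys <- key(surv$roi_a, surv$roi_b)
  d <- distances[cbind(match(all_e$roi_a, rownames(distances)),
                       match(all_e$roi_b, rownames(distances)))]
  is_true <- all_keys %in% true_keys
  is_surv <- all_keys %in% surv_keys
  strat <- function(sel) {
    pos <- sum(sel & is_true); neg <- sum(sel & !is_true)
    list(sens = sum(sel & is_true & is_surv) / pos,
         spec = sum(sel & !is_true & !is_surv) / neg)
  }
  ov <- strat(rep(TRUE, length(is_true)))
  sh <- strat(d < distance_cut)
  lo <- strat(d >= distance_cut)
  list(sensitivity = ov$sens, specificity = ov$spec,
       sensitivity_short = sh$sens, sensitivity_long = lo$sens,
       specificity_short = sh$spec, specificity_long = lo$spec,
       n_surviving = sum(is_surv))
}

#' One replicate of the planted-bundle recovery experiment
#'
#' Simulates a cohort, averages the subject matrices, fits the
#' distance-dependent model on the group-average pair scores, thresholds the
#' group matrix at `alpha`, and compares long-range bundle recovery against a
#' uniform cutoff matched to the same number of surviving edges.
#'
#' @param seed Replicate seed (fed to the generator; the model seed is derived
#'   from it).
#' @param cfg Generator configuration (the seed inside is replaced).
#' @param min_samples Minimum samples per distance bin for the null model.
#' @param alphas Alpha levels fitted.
#' @param alpha Alpha level evaluated.
#' @param n_draws Monte-Carlo draws per bin.
#' @param distance_cut Short/long stratification boundary, mm.
#' @return A list: `ddd` and `baseline` recovery metrics (see
#'   [evaluate_recovery()]), `n_surviving`, `n_bins`.
#' @export
recovery_experiment <- function(seed = 1, cfg = generator_config(),
                                min_samples = 150,
                                alphas = c(0.1, 0.2, 0.3), alpha = 0.1,
                                n_draws = 1e5, distance_cut = 80) {
  cfg$seed <- as.integer(seed)
  sim <- simulate_cohort(cfg)
  avg <- group_average(sim$matrices)
  ut <- which(upper.tri(avg), arr.ind = TRUE)
  pair_scores <- data.frame(distance = sim$distances[ut], score = avg[ut])
  binning <- build_bins(pair_scores$distance, min_samples = min_samples)
  model <- fit_ddd(binning, pair_scores, alphas = alphas, n_draws = n_draws,
                   seed = seed)
  net <- apply_ddd(model, avg, sim$distances)
  k <- nrow(surviving_edges(net, alpha))
  base <- match_count_threshold(avg, k)
  list(
    ddd = evaluate_recovery(sim$truth, net, sim$distances, distance_cut,
                            alpha = alpha),
    baseline = evaluate_recovery(sim$truth, base, sim$distances,
                                 distance_cut),
    n_surviving = k,
    n_bins = nrow(binning$bins)
  )
}
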