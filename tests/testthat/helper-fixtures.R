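# shared in-code fixtures; everything is generated, nothing read from disk
# except the packaged language-ROI distance matrix

# two well-separated ROIs plus a distant third
three_rois <- function(space_tag = "MNI152") {
  roi_set(c("A", "B", "C"),
          x = c(0, 40, 0), y = c(0, 0, 80), z = 0,
          radius = 8, space_tag = space_tag)
}

# a straight streamline between two points (n interior vertices)
straight_streamline <- function(p0, p1, n_points = 5) {
  tt <- seq(0, 1, length.out = n_points)
  outer(1 - tt, p0) + outer(tt, p1)
}

# tractogram with counts of A-B streamlines and one-ended extras; used to
# construct exact denominators for connection scores
score_fixture_tractogram <- function(n_ab, n_a_only, n_b_only,
                                     rois = three_rois()) {
  ctr <- as.matrix(rois[, c("x", "y", "z")])
  rownames(ctr) <- rois$id
  far <- c(0, 0, 500)  # far from every ROI, never assigned
  sl <- c(
    replicate(n_ab, straight_streamline(ctr["A", ], ctr["B", ]),
              simplify = FALSE),
    replicate(n_a_only, straight_streamline(ctr["A", ], far),
              simplify = FALSE),
    replicate(n_b_only, straight_streamline(ctr["B", ], far),
              simplify = FALSE)
  )
  tractogram(sl, subject_id = "fix", space_tag = roi_space(rois),
             max_length_mm = 1000)
}

roi_space <- function(rois) attr(rois, "space_tag")

# zero-inflated, tie-rich candidate scores: proportions k/denominator, the
# shape connection scores actually take
make_tied_candidates <- function(n = 2000, denom = 200, zero_frac = 0.4,
                                 seed = 99) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    k <- rbinom(n, denom, 0.08)
    k[runif(n) < zero_frac] <- 0L
    k / denom
  })
}

# brute-force oracle for the nearest-rank-lower threshold: scan every
# candidate value, return the smallest with fraction strictly above <= alpha
oracle_threshold <- function(draws, alpha) {
  for (t in sort(unique(draws))) {
    if (mean(draws > t) <= alpha + 1e-12) return(t)
  }
  max(draws)
}

# in-code binary NIfTI mask: 1 mm isotropic voxels, world coordinate of
# voxel (i,j,k) (0-based) is its index (identity affine)
unit_mask <- function(dims, on_voxels = NULL) {
  arr <- array(0, dim = dims)
  if (!is.null(on_voxels)) {
    arr[as.matrix(on_voxels) + 1] <- 1
  }
  img <- RNifti::asNifti(arr)
  img  # default xform is identity-scaled; pixdim 1
}
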