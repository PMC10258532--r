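test_that("termini are captured by the sphere-plus-search zone", {
  rois <- roi_set("A", 0, 0, 0, radius = 8)
  mk <- function(z_end) tractogram(
    list(straight_streamline(c(0, 0, 200), c(0, 0, z_end))),
    max_length_mm = 1000)
  # terminus at the centre
  expect_identical(assign_endpoints(mk(0), rois, 4)$end_roi, "A")
  # 11 mm from centre: within radius 8 + search 4
  expect_identical(assign_endpoints(mk(11), rois, 4)$end_roi, "A")
  # 13 mm from centre: outside the capture zone
  expect_identical(assign_endpoints(mk(13), rois, 4)$end_roi, NA_character_)
})

test_that("capture ties go to the nearest centre, then lexicographic id", {
  rois <- roi_set(c("B", "A", "near"), x = c(-10, 10, 3), y = 0, z = 0,
                  radius = 8)
  tr <- tractogram(list(straight_streamline(c(0, 0, 100), c(0, 0, 0))),
                   max_length_mm = 1000)
  # 'near' is closest
  expect_identical(assign_endpoints(tr, rois, 4)$end_roi, "near")
  two <- roi_set(c("B", "A"), x = c(-10, 10), y = 0, z = 0, radius = 8)
  # equidistant: lexicographically first id wins
  expect_identical(assign_endpoints(tr, two, 4)$end_roi, "A")
})

test_that("interior streamline points never contribute to assignment", {
  rois <- roi_set("mid", 0, 0, 0, radius = 8)
  # passes straight through the sphere, termini far away
  through <- tractogram(list(straight_streamline(c(0, 0, -100), c(0, 0, 100),
                                                 n_points = 51)),
                        max_length_mm = 1000)
  asg <- assign_endpoints(through, rois, 4)
  expect_true(is.na(asg$start_roi) && is.na(asg$end_roi))
})

test_that("connection score averages the two directed proportions", {
  # 2 A-B streamlines; A touched by 10 total, B by 20: mean(2/10, 2/20)
  tr <- score_fixture_tractogram(n_ab = 2, n_a_only = 8, n_b_only = 18)
  asg <- assign_endpoints(tr, three_rois(), 4)
  expect_equal(connection_score(asg, "A", "B"), 0.15)
  expect_equal(connection_score(asg, "B", "A"), 0.15)
  # untouched pair scores 0
  expect_equal(connection_score(asg, "A", "C"), 0)
  expect_error(connection_score(asg, "A", "A"), "diagonal")
})

test_that("maximal connection score is 1", {
  tr <- score_fixture_tractogram(n_ab = 5, n_a_only = 0, n_b_only = 0)
  asg <- assign_endpoints(tr, three_rois(), 4)
  expect_equal(connection_score(asg, "A", "B"), 1)
})

test_that("connectivity_matrix is symmetric in [0,1] with zero diagonal", {
  rois <- three_rois()
  empty <- tractogram(list(), subject_id = "none")
  m0 <- connectivity_matrix(empty, rois)
  expect_true(all(m0 == 0))

  one <- score_fixture_tractogram(1, 0, 0)
  m1 <- connectivity_matrix(one, rois)
  expect_equal(m1["A", "B"], 1)
  expect_equal(sum(m1 > 0), 2)  # the symmetric pair only

  # random tractograms keep the invariants
  for (s in 1:3) {
    counts <- data.frame(roi_a = c("A", "A", "B"), roi_b = c("B", "C", "C"),
                         n = sample(0:4, 3, replace = TRUE))
    tr <- simulate_tractogram(rois, counts, n_background = 3, seed = s)
    m <- connectivity_matrix(tr, rois)
    expect_identical(unname(unclass(m)), unname(t(unclass(m))))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("permuting the ROI set permutes rows and columns identically", {
  rois <- three_rois()
  tr <- score_fixture_tractogram(2, 3, 1)
  m <- connectivity_matrix(tr, rois)
  perm <- rois[c(3, 1, 2), , drop = FALSE]
  attr(perm, "space_tag") <- attr(rois, "space_tag")
  class(perm) <- class(rois)
  mp <- connectivity_matrix(tr, perm)
  expect_equal(unclass(mp)[rownames(m), colnames(m)], unclass(m)[, ],
               ignore_attr = TRUE)
})

test_that("removing all streamlines touching an ROI zeroes its row/column", {
  rois <- three_rois()
  ctr <- as.matrix(rois[, c("x", "y", "z")]); rownames(ctr) <- rois$id
  sl_ab <- replicate(3, straight_streamline(ctr["A", ], ctr["B", ]),
                     simplify = FALSE)
  sl_c <- list(straight_streamline(ctr["C", ], c(0, 0, 400)))
  full <- tractogram(c(sl_ab, sl_c), max_length_mm = 1000)
  drop_b <- tractogram(sl_c, max_length_mm = 1000)
  mf <- connectivity_matrix(full, rois)
  md <- connectivity_matrix(drop_b, rois)
  expect_true(all(md["B", ] == 0) && all(md[, "B"] == 0))
  # pairs not involving A or B are untouched (none of the removed
  # streamlines touched C)
  expect_equal(md["A", "C"], mf["A", "C"])
})

test_that("minimum streamline length per pair and group distance", {
  rois <- three_rois()
  ctr <- as.matrix(rois[, c("x", "y", "z")]); rownames(ctr) <- rois$id
  # three A-B streamlines with distinct detour lengths
  bent <- function(detour) rbind(ctr["A", ], c(20, detour, 0), ctr["B", ])
  tr <- tractogram(list(bent(0), bent(30), bent(60)), max_length_mm = 1000)
  asg <- assign_endpoints(tr, rois, 4)
  lens <- sort(asg$length_mm)
  expect_equal(pair_min_streamline_length(asg, "A", "B"), lens[1])
  expect_true(is.na(pair_min_streamline_length(asg, "A", "C")))
  expect_error(pair_min_streamline_length(asg, "A", "A"), "differ")

  expect_identical(streamline_distance_group(c(40.2, 39.8)), 40L)
  expect_identical(streamline_distance_group(c(30, NA, 50)), 40L)
  expect_true(is.na(streamline_distance_group(c(NA_real_, NA_real_))))
})

test_that("streamline length bounds the terminus separation from below", {
  rois <- three_rois()
  counts <- data.frame(roi_a = "A", roi_b = "C", n = 10)
  tr <- simulate_tractogram(rois, counts, jitter_mm = 2, seed = 11)
  for (s in tr$streamlines) {
    sep <- sqrt(sum((s[1, ] - s[nrow(s), ])^2))
    expect_gte(polyline_length(s), sep - 1e-9)
  }
})

test_that("cohort streamline distances track Euclidean distances", {
  # same-geometry cohort: streamline distance should rank like Euclidean
  set.seed(5)
  rois <- roi_set(sprintf("r%d", 1:5),
                  x = c(0, 30, 70, 10, 50), y = c(0, 10, 40, 60, 80), z = 0,
                  radius = 6)
  pairs <- t(combn(rois$id, 2))
  counts <- data.frame(roi_a = pairs[, 1], roi_b = pairs[, 2], n = 3)
  tracts <- lapply(1:3, function(s)
    simulate_tractogram(rois, counts, jitter_mm = 1.5, seed = s,
                        subject_id = paste0("s", s)))
  sd_mat <- streamline_distance_matrix(tracts, rois)
  ed_mat <- distance_matrix(rois)
  ut <- upper.tri(sd_mat)
  rho <- cor(sd_mat[ut], ed_mat[ut], method = "spearman")
  expect_gt(rho, 0.9)
  # arc length >= straight line, so streamline distance is never much shorter
  expect_true(all(sd_mat[ut] >= ed_mat[ut] - 2 * max(rois$radius)))
})
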