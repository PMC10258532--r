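#' Round half away from zero
#'
#' Inter-ROI distances are reported as integer millimetres. Base R's
#' [round()] rounds halves to even, so matrices would depend on the platform's
#' binary representation of `.5` values; a fixed half-away-from-zero rule keeps
#' distance matrices bit-reproducible (16.5 mm -> 17 mm).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @examples
#' round_half_away(c(16.5, -16.5, 2.4))
#' @export
round_half_away <- function(x) {
  out <- sign(x) * floor(abs(x) + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Euclidean centre-to-centre distance between two ROIs, integer mm
#'
#' @param a,b Single-row subsets of an [roi_set()] (or any list/data frame with
#'   `x`, `y`, `z` fields).
#' @param space_a,space_b Optional space tags; when both are supplied and
#'   differ the call is rejected.
#' @return Integer mm distance, rounded half away from zero. Symmetric in its
#'   arguments.
#' @examples
#' r <- roi_set(c("a", "b"), x = c(0, 3), y = c(0, 4), z = 0)
#' euclidean_pair_distance(r[1, ], r[2, ]) # 5
#' @export
euclidean_pair_distance <- function(a, b, space_a = NULL, space_b = NULL) {
  if (!is.null(space_a) && !is.null(space_b) && !identical(space_a, space_b)) {
    stop("space mismatch: '", space_a, "' vs '", space_b, "'", call. = FALSE)
  }
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  round_half_away(d)
}

#' Pairwise Euclidean distance matrix for an ROI set
#'
#' Computes centre-to-centre Euclidean distances for all ROI pairs, rounded to
#' integer millimetres. The result carries the set's id ordering and a
#' `measure` attribute so it can be matched against a fitted null model.
#'
#' @param rois An [roi_set()] with at least two ROIs.
#' @return An integer matrix of class `ddd_distance_matrix` with ROI ids as
#'   dimnames, zero diagonal, and attribute `measure = "euclidean"`.
#' @export
distance_matrix <- function(rois) {
  if (nrow(rois) < 2) stop("need at least 2 ROIs", call. = FALSE)
  d <- as.matrix(stats::dist(roi_centres(rois)))
  m <- round_half_away(d)
  dim(m) <- dim(d)
  dimnames(m) <- list(rois$id, rois$id)
  new_distance_matrix(m, measure = "euclidean")
}

new_distance_matrix <- function(m, measure) {
  measure <- match.arg(measure, c("euclidean", "streamline"))
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(m[!is.na(m)] < 0)) stop("distances must be >= 0", call. = FALSE)
  attr(m, "measure") <- measure
  class(m) <- c("ddd_distance_matrix", class(m))
  m
}

distance_measure <- function(d) attr(d, "measure") %||% "euclidean"

#' @export
print.ddd_distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, measure = %s\n",
              nrow(x), ncol(x), distance_measure(x)))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(y[seq_len(min(8, nrow(y))), seq_len(min(8, ncol(y))), drop = FALSE])
  invisible(x)
}

#' Packaged 13-ROI language-network distance fixture
#'
#' Loads the packaged integer-mm Euclidean distance matrix between 13
#' left-hemisphere language ROIs (fusiform, temporal, inferior frontal,
#' premotor, supramarginal and anterior-temporal regions) used in the worked
#' examples and tests.
#'
#' @return A 13 x 13 `ddd_distance_matrix` (measure `"euclidean"`).
#' @examples
#' d <- language_distance_fixture()
#' max(d[upper.tri(d)])
#' @export
language_distance_fixture <- function() {
  path <- system.file("extdata", "language_rois_distance_mm.csv",
                      package = "dddthresh")
  read_distance_matrix(path)
}
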