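#' Construct a tractogram
#'
#' A tractogram is a subject-labelled collection of streamlines, each a 3D
#' polyline stored as an n x 3 matrix of mm coordinates.
#'
#' @param streamlines List of numeric matrices, each with >= 2 rows and 3
#'   columns (x, y, z in mm).
#' @param subject_id Non-empty subject identifier.
#' @param space_tag Coordinate-space tag; must match the ROI set used for
#'   endpoint assignment.
#' @param max_length_mm Maximum admissible streamline arc length (the tracking
#'   default is 250 mm); longer streamlines are rejected.
#'
#' @return A list of class `tractogram` with elements `subject_id`,
#'   `streamlines`, `space_tag`.
#' @export
tractogram <- function(streamlines, subject_id = "subject",
                       space_tag = "MNI152", max_length_mm = 250) {
  if (!nzchar(subject_id)) stop("subject_id must be non-empty", call. = FALSE)
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3 || nrow(s) < 2) {
      stop("each streamline needs >= 2 points with 3 coordinates",
           call. = FALSE)
    }
    storage.mode(s) <- "double"
    s
  })
  lens <- vapply(streamlines, polyline_length, numeric(1))
  if (any(lens > max_length_mm + 1e-6)) {
    stop("streamline(s) exceed max length of ", max_length_mm, " mm",
         call. = FALSE)
  }
  structure(list(subject_id = subject_id, streamlines = streamlines,
                 space_tag = space_tag),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> subject '%s': %d streamlines in space '%s'\n",
              x$subject_id, length(x$streamlines), x$space_tag))
  invisible(x)
}

#' Arc length of a polyline
#'
#' @param points An n x 3 matrix of mm coordinates.
#' @return Sum of consecutive point-to-point Euclidean distances, in mm.
#' @export
polyline_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) return(0)
  seg <- diff(points)
  sum(sqrt(rowSums(seg^2)))
}

#' Assign streamline termini to ROIs with a radial search zone
#'
#' Only the two termini of each streamline are considered (a streamline merely
#' passing through an ROI never contributes). A terminus is captured by an ROI
#' when it lies within `search_mm` of the sphere surface, i.e. when the
#' centre distance is at most `radius + search_mm`. When several ROIs capture
#' the same terminus, the one with the smallest centre distance wins; exact
#' ties are broken by lexicographic ROI id.
#'
#' @param tract A [tractogram()].
#' @param rois An [roi_set()] in the same space.
#' @param search_mm Radial search distance in mm (tracking-tool default 4).
#'
#' @return A data frame of class `endpoint_assignment` with one row per
#'   streamline: `streamline` (index), `start_roi`, `end_roi` (ROI id or
#'   `NA`), and `length_mm` (polyline arc length).
#' @export
assign_endpoints <- function(tract, rois, search_mm = 4) {
  if (search_mm < 0) stop("search_mm must be >= 0", call. = FALSE)
  if (!identical(tract$space_tag, roi_space(rois))) {
    stop("space mismatch: tractogram '", tract$space_tag, "' vs ROI set '",
         roi_space(rois), "'", call. = FALSE)
  }
  n <- length(tract$streamlines)
  centres <- roi_centres(rois)
  capture <- rois$radius + search_mm
  ord_ids <- rois$id

  assign_one <- function(p) {
    if (nrow(rois) == 0) return(NA_character_)
    d <- sqrt(colSums((t(centres) - p)^2))
    ok <- d <= capture
    if (!any(ok)) return(NA_character_)
    cand <- which(ok)
    best <- cand[d[cand] == min(d[cand])]
    if (length(best) > 1) best <- best[order(ord_ids[best])][1]
    ord_ids[best]
  }

  start_roi <- character(n); end_roi <- character(n); len <- numeric(n)
  for (i in seq_len(n)) {
    s <- tract$streamlines[[i]]
    start_roi[i] <- assign_one(s[1, ])
    end_roi[i] <- assign_one(s[nrow(s), ])
    len[i] <- polyline_length(s)
  }
  out <- data.frame(streamline = seq_len(n), start_roi = start_roi,
                    end_roi = end_roi, length_mm = len,
                    stringsAsFactors = FALSE)
  class(out) <- c("endpoint_assignment", "data.frame")
  out
}

# streamlines with >= 1 terminus assigned to `roi` (a both-ends-in-roi
# streamline counts once and contributes to no pair)
touches_roi <- function(asg, roi) {
  (!is.na(asg$start_roi) & asg$start_roi == roi) |
    (!is.na(asg$end_roi) & asg$end_roi == roi)
}

connects_pair <- function(asg, a, b) {
  (!is.na(asg$start_roi) & !is.na(asg$end_roi)) &
    ((asg$start_roi == a & asg$end_roi == b) |
       (asg$start_roi == b & asg$end_roi == a))
}

#' Connection score between two ROIs
#'
#' The directed score seed -> target is the proportion of streamlines with a
#' terminus in the seed ROI whose other terminus lands in the target ROI; the
#' reported score is the mean of the two directed scores. A direction with no
#' streamline touching its seed contributes 0. Scores therefore lie in
#' \[0, 1\].
#'
#' @param asg An [assign_endpoints()] result.
#' @param seed,target Distinct ROI ids.
#' @return Numeric score in \[0, 1\].
#' @examples
#' # 10 streamlines touch A (2 reaching B), 20 touch B (2 reaching A):
#' # mean(2/10, 2/20) = 0.15
#' @export
connection_score <- function(asg, seed, target) {
  if (identical(seed, target)) {
    stop("self-connections are undefined (diagonal is fixed at 0)",
         call. = FALSE)
  }
  n_pair <- sum(connects_pair(asg, seed, target))
  directed <- function(s) {
    denom <- sum(touches_roi(asg, s))
    if (denom == 0) 0 else n_pair / denom
  }
  mean(c(directed(seed), directed(target)))
}

#' Connectivity matrix from a tractogram
#'
#' Applies [connection_score()] to every unordered ROI pair, producing a
#' symmetric matrix with zero diagonal and entries in \[0, 1\].
#'
#' @param tract A [tractogram()].
#' @param rois An [roi_set()] in the same space.
#' @param search_mm Radial search distance in mm.
#' @return A `connectivity_matrix` (see [as_connectivity_matrix()]) tagged with
#'   the tractogram's subject id.
#' @export
connectivity_matrix <- function(tract, rois, search_mm = 4) {
  asg <- assign_endpoints(tract, rois, search_mm)
  ids <- rois$id
  k <- length(ids)
  touch <- vapply(ids, function(r) sum(touches_roi(asg, r)), numeric(1))
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k >= 2) {
    conn <- asg[!is.na(asg$start_roi) & !is.na(asg$end_roi) &
                  asg$start_roi != asg$end_roi, , drop = FALSE]
    if (nrow(conn) > 0) {
      key <- ifelse(conn$start_roi < conn$end_roi,
                    paste(conn$start_roi, conn$end_roi, sep = "\r"),
                    paste(conn$end_roi, conn$start_roi, sep = "\r"))
      counts <- table(key)
      for (kk in names(counts)) {
        ab <- strsplit(kk, "\r", fixed = TRUE)[[1]]
        n_pair <- as.numeric(counts[[kk]])
        s1 <- if (touch[ab[1]] == 0) 0 else n_pair / touch[ab[1]]
        s2 <- if (touch[ab[2]] == 0) 0 else n_pair / touch[ab[2]]
        m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- mean(c(s1, s2))
      }
    }
  }
  as_connectivity_matrix(m, subject_id = tract$subject_id)
}

#' Validate and tag a connectivity matrix
#'
#' @param m Square numeric matrix with ROI ids as dimnames; must be symmetric
#'   with zero diagonal and entries in \[0, 1\].
#' @param subject_id Subject identifier or group tag.
#' @param n_subjects Number of subjects averaged into the matrix.
#' @return The matrix with class `connectivity_matrix` and attributes
#'   `subject_id`, `n_subjects`.
#' @export
as_connectivity_matrix <- function(m, subject_id = "subject", n_subjects = 1L) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (is.null(rownames(m))) stop("matrix must carry ROI ids", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE, tolerance = 1e-9))) {
    stop("connectivity matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  diag(m) <- 0
  attr(m, "subject_id") <- subject_id
  attr(m, "n_subjects") <- as.integer(n_subjects)
  class(m) <- c("connectivity_matrix", class(m))
  m
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d ROIs, subject '%s' (n = %d)\n",
              nrow(x), attr(x, "subject_id"), attr(x, "n_subjects")))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(signif(y[seq_len(min(6, nrow(y))), seq_len(min(6, ncol(y))),
                 drop = FALSE], 3))
  invisible(x)
}

#' Minimum connecting-streamline length for an ROI pair
#'
#' @param asg An [assign_endpoints()] result (carries per-streamline lengths).
#' @param a,b Distinct ROI ids.
#' @return Minimum arc length (mm) over streamlines whose two termini are
#'   assigned to `a` and `b`, or `NA` when no streamline connects the pair.
#' @export
pair_min_streamline_length <- function(asg, a, b) {
  if (identical(a, b)) stop("a and b must differ", call. = FALSE)
  sel <- connects_pair(asg, a, b)
  if (!any(sel)) return(NA_real_)
  min(asg$length_mm[sel])
}

#' Group streamline distance from per-subject minima
#'
#' The streamline distance of an ROI pair is the mean over subjects of each
#' subject's minimum connecting-streamline length, rounded to integer mm.
#' Subjects with no connecting streamline are treated as missing and dropped
#' from the average; when every subject is missing the distance is `NA`.
#'
#' @param minima Numeric vector of per-subject minimum lengths (mm), `NA` for
#'   subjects without a connecting streamline.
#' @return Integer mm distance or `NA`.
#' @examples
#' streamline_distance_group(c(40.2, 39.8)) # 40
#' streamline_distance_group(c(30, NA, 50)) # 40
#' @export
streamline_distance_group <- function(minima) {
  if (length(minima) < 1) stop("need >= 1 subject", call. = FALSE)
  ok <- !is.na(minima)
  if (!any(ok)) return(NA_integer_)
  round_half_away(mean(minima[ok]))
}

#' Streamline distance matrix for a cohort of tractograms
#'
#' Convenience wrapper: assigns endpoints per subject, takes per-subject
#' minimum connecting-streamline lengths for every ROI pair, and averages them
#' with [streamline_distance_group()]. Pairs unconnected in every subject get
#' `NA`.
#'
#' @param tracts List of [tractogram()]s (one per subject).
#' @param rois An [roi_set()].
#' @param search_mm Radial search distance in mm.
#' @return A `ddd_distance_matrix` with `measure = "streamline"`; the diagonal
#'   is `NA` (self-distances are undefined for this measure).
#' @export
streamline_distance_matrix <- function(tracts, rois, search_mm = 4) {
  ids <- rois$id
  k <- length(ids)
  per_subject <- lapply(tracts, function(tr) {
    asg <- assign_endpoints(tr, rois, search_mm)
    m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
    conn <- asg[!is.na(asg$start_roi) & !is.na(asg$end_roi) &
                  asg$start_roi != asg$end_roi, , drop = FALSE]
    for (r in seq_len(nrow(conn))) {
      a <- conn$start_roi[r]; b <- conn$end_roi[r]; l <- conn$length_mm[r]
      cur <- m[a, b]
      if (is.na(cur) || l < cur) m[a, b] <- m[b, a] <- l
    }
    m
  })
  out <- matrix(NA_integer_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      minima <- vapply(per_subject, function(m) m[i, j], numeric(1))
      out[i, j] <- out[j, i] <- streamline_distance_group(minima)
    }
  }
  new_distance_matrix(out, measure = "streamline")
}
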