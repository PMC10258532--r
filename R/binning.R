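#' Group integer distances into bins with a minimum sample count
#'
#' Pair samples are pooled into contiguous distance bins so that each bin's
#' empirical null distribution rests on enough samples. A greedy left-to-right
#' scan over the sorted unique distances accumulates consecutive distances
#' until the running sample count reaches `min_samples`, then closes the bin.
#' If the final bin would fall short it is merged into the previous one, so no
#' under-powered bin survives at the longest distances (the merge is flagged).
#'
#' @param distances Integer vector of per-sample distances (one entry per ROI
#'   pair sample); `NA`s are dropped.
#' @param min_samples Minimum samples per bin (>= 1). Typical values: 1000 for
#'   Euclidean distances, 1500 for streamline distances.
#' @param measure Distance measure the samples came from.
#'
#' @return A list of class `distance_binning`: `bins` (data frame `lo`, `hi`,
#'   `n_samples`), `measure`, `min_samples`, and logical flags
#'   `terminal_merged` (last bin absorbed a shortfall) and `under_min` (total
#'   samples below `min_samples`, producing a single flagged bin).
#' @examples
#' b <- build_bins(rep(1:10, each = 500), min_samples = 1000)
#' b$bins # five bins of 1000 samples
#' @export
build_bins <- function(distances, min_samples,
                       measure = c("euclidean", "streamline")) {
  measure <- match.arg(measure)
  if (min_samples < 1) stop("min_samples must be >= 1", call. = FALSE)
  distances <- distances[!is.na(distances)]
  if (length(distances) < 1) stop("need >= 1 sample", call. = FALSE)
  tab <- table(distances)
  uniq <- as.integer(names(tab))
  counts <- as.integer(tab)

  under_min <- sum(counts) < min_samples
  lo <- integer(0); hi <- integer(0); n <- integer(0)
  acc <- 0L; start <- uniq[1]
  for (i in seq_along(uniq)) {
    acc <- acc + counts[i]
    if (acc >= min_samples) {
      lo <- c(lo, start); hi <- c(hi, uniq[i]); n <- c(n, acc)
      acc <- 0L
      if (i < length(uniq)) start <- uniq[i + 1]
    }
  }
  terminal_merged <- FALSE
  if (acc > 0L) {
    if (length(lo) == 0) {
      lo <- start; hi <- uniq[length(uniq)]; n <- acc
    } else {
      hi[length(hi)] <- uniq[length(uniq)]
      n[length(n)] <- n[length(n)] + acc
      terminal_merged <- TRUE
    }
  }
  structure(list(
    bins = data.frame(lo = lo, hi = hi, n_samples = n),
    measure = measure,
    min_samples = as.integer(min_samples),
    terminal_merged = terminal_merged,
    under_min = under_min
  ), class = "distance_binning")
}

#' @export
print.distance_binning <- function(x, ...) {
  cat(sprintf("<distance_binning> %d bins (%s, min %d samples%s)\n",
              nrow(x$bins), x$measure, x$min_samples,
              if (x$terminal_merged) ", terminal merge" else ""))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Locate the bin containing (or nearest to) a distance
#'
#' Distances below the first bin clamp to the first bin and distances above
#' the last clamp to the last; a distance falling in a gap between bins (a
#' distance value unobserved when the bins were built) goes to the nearest bin
#' by boundary distance, the lower bin on ties.
#'
#' @param binning A [build_bins()] result.
#' @param d Integer distance(s), mm.
#' @return Integer bin index (1-based), vectorised over `d`.
#' @export
locate_bin <- function(binning, d) {
  bins <- binning$bins
  if (nrow(bins) == 0) stop("empty binning", call. = FALSE)
  vapply(d, function(di) {
    if (is.na(di)) return(NA_integer_)
    if (di <= bins$hi[1] || nrow(bins) == 1) {
      if (di >= bins$lo[1]) {
        inside <- which(bins$lo <= di & di <= bins$hi)
        if (length(inside)) return(inside[1])
      }
      return(1L)
    }
    if (di >= bins$lo[nrow(bins)]) {
      inside <- which(bins$lo <= di & di <= bins$hi)
      if (length(inside)) return(inside[length(inside)])
      return(nrow(bins))
    }
    inside <- which(bins$lo <= di & di <= bins$hi)
    if (length(inside)) return(inside[1])
    # in a gap: nearest boundary, lower bin on ties
    below <- max(which(bins$hi < di))
    above <- min(which(bins$lo > di))
    if ((di - bins$hi[below]) <= (bins$lo[above] - di)) below else above
  }, integer(1))
}

#' Serialize a binning to JSON
#'
#' @param binning A [build_bins()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binning_json <- function(binning, path) {
  jsonlite::write_json(list(
    measure = binning$measure,
    min_samples = binning$min_samples,
    terminal_merged = binning$terminal_merged,
    under_min = binning$under_min,
    bins = binning$bins
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a binning from JSON
#'
#' @param path File written by [write_binning_json()].
#' @return A `distance_binning`.
#' @export
read_binning_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    bins = data.frame(lo = as.integer(x$bins$lo), hi = as.integer(x$bins$hi),
                      n_samples = as.integer(x$bins$n_samples)),
    measure = x$measure,
    min_samples = as.integer(x$min_samples),
    terminal_merged = isTRUE(x$terminal_merged),
    under_min = isTRUE(x$under_min)
  ), class = "distance_binning")
}
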