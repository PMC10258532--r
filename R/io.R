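#' Read an ROI table
#'
#' Reads a tab-separated table with header
#' `id<TAB>x<TAB>y<TAB>z<TAB>radius<TAB>label` (label optional) into an
#' [roi_set()], preserving row order. Malformed rows are reported with their
#' line number; duplicate ids are rejected.
#'
#' @param path TSV file path.
#' @param space_tag Coordinate-space tag to attach.
#' @return An [roi_set()] (possibly empty, with a warning, for a header-only
#'   file).
#' @export
read_roi_table <- function(path, space_tag = "MNI152") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  required <- c("id", "x", "y", "z", "radius")
  if (!all(required %in% header)) {
    stop("ROI table header must contain: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("ROI table has no data rows: ", path)
    return(roi_set(character(0), numeric(0), numeric(0), numeric(0),
                   radius = numeric(0), space_tag = space_tag))
  }
  for (col in c("x", "y", "z", "radius")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("malformed value in column '", col, "' at line ", bad[1] + 1,
           " of ", path, call. = FALSE)
    }
    df[[col]] <- vals
  }
  label <- if ("label" %in% names(df)) df$label else NA_character_
  suppressMessages(
    roi_set(df$id, df$x, df$y, df$z, radius = df$radius, label = label,
            space_tag = space_tag)
  )
}

#' Write an ROI table
#'
#' @param rois An [roi_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  utils::write.table(as.data.frame(rois), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_square_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square",
                               call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column ids differ in ", path, call. = FALSE)
  }
  m
}

#' Read a connectivity matrix from CSV
#'
#' Expects a square CSV with matching ROI ids as first row and column.
#' Asymmetries within `tol` are repaired by averaging with the transpose;
#' larger asymmetries are rejected.
#'
#' @param path CSV path.
#' @param subject_id Subject/group tag to attach.
#' @param n_subjects Number of subjects behind the matrix.
#' @param tol Symmetry tolerance.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_matrix <- function(path, subject_id = basename(path),
                                     n_subjects = 1L, tol = 1e-9) {
  m <- read_square_csv(path)
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop("matrix in ", path, " asymmetric beyond tolerance (max |m - t(m)| = ",
         format(asym), ")", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  as_connectivity_matrix(m, subject_id = subject_id, n_subjects = n_subjects)
}

#' Read an integer distance matrix from CSV
#'
#' @param path CSV path (square, ROI ids as first row/column, integer mm
#'   entries; `NA` allowed for missing streamline distances).
#' @param measure Distance measure of the stored values.
#' @return A `ddd_distance_matrix`.
#' @export
read_distance_matrix <- function(path, measure = c("euclidean", "streamline")) {
  measure <- match.arg(measure)
  m <- read_square_csv(path)
  if (any(abs(m - round(m)) > 0, na.rm = TRUE)) {
    stop("distance matrix in ", path, " has non-integer entries",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  new_distance_matrix(m, measure = measure)
}

#' Write a matrix (connectivity or distance) to CSV
#'
#' ROI ids are written as the first row and column; round-trips are lossless
#' at the stored precision (integers exactly, scores at 15 significant
#' digits).
#'
#' @param m A `connectivity_matrix` or `ddd_distance_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  y <- m
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  df <- as.data.frame(y, check.names = FALSE)
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a thresholded network edge list to TSV
#'
#' Columns: `roi_a`, `roi_b`, `score`, `distance_mm`, `bin`, `tier` (empty
#' tier means the edge survives at no alpha).
#'
#' @param net A [apply_ddd()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write an endpoint assignment to TSV
#'
#' Columns `streamline_index`, `start_roi`, `end_roi`, with `-` for
#' unassigned termini.
#'
#' @param asg An [assign_endpoints()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(asg, path) {
  out <- data.frame(streamline_index = asg$streamline,
                    start_roi = ifelse(is.na(asg$start_roi), "-",
                                       asg$start_roi),
                    end_roi = ifelse(is.na(asg$end_roi), "-", asg$end_roi))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- streamline formats -----------------------------------------------------

#' Read streamlines from a plain-text block format
#'
#' One streamline per block: a `# id` line followed by `x y z` lines. Blocks
#' are separated by the next `#` line; blank lines are ignored.
#'
#' @param path Text file path.
#' @param subject_id,space_tag Passed to [tractogram()].
#' @param max_length_mm Maximum admissible streamline length.
#' @return A [tractogram()].
#' @export
read_streamlines_text <- function(path, subject_id = "subject",
                                  space_tag = "MNI152", max_length_mm = 250) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^#", lines)
  if (length(starts) == 0) stop("no '# id' blocks in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1, length(lines))
  sl <- lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):ends[i]]
    pts <- do.call(rbind, lapply(block, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    if (is.null(pts) || ncol(pts) != 3) {
      stop("malformed streamline block ", i, " in ", path, call. = FALSE)
    }
    pts
  })
  tractogram(sl, subject_id = subject_id, space_tag = space_tag,
             max_length_mm = max_length_mm)
}

#' Write streamlines to the plain-text block format
#'
#' @param tract A [tractogram()].
#' @param path Output text path.
#' @return `path`, invisibly.
#' @export
write_streamlines_text <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(tract$streamlines)) {
    writeLines(sprintf("# %d", i), con)
    s <- tract$streamlines[[i]]
    writeLines(apply(s, 1, function(p)
      paste(format(p, trim = TRUE, digits = 15), collapse = " ")), con)
  }
  invisible(path)
}

#' Read an MRtrix track (TCK) file
#'
#' Parses the text header (`mrtrix tracks` magic, `key: value` lines up to
#' `END`) and the float32 little-endian triplet stream, in which
#' `(NaN, NaN, NaN)` separates streamlines and `(Inf, Inf, Inf)` terminates
#' the file.
#'
#' @param path TCK file path.
#' @param subject_id,space_tag Passed to [tractogram()].
#' @param max_length_mm Maximum admissible streamline length.
#' @return A [tractogram()].
#' @export
read_tck <- function(path, subject_id = "subject", space_tag = "MNI152",
                     max_length_mm = 250) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))
  if (length(nl) == 0) stop("unterminated TCK header", call. = FALSE)
  magic <- rawToChar(raw[seq_len(nl[1] - 1)])
  if (!identical(trimws(magic), "mrtrix tracks")) {
    stop(path, " is not an MRtrix track file", call. = FALSE)
  }
  offset <- NULL
  datatype <- "Float32LE"
  prev <- nl[1]
  for (pos in nl[-1]) {
    line <- rawToChar(raw[(prev + 1):(pos - 1)])
    prev <- pos
    if (identical(trimws(line), "END")) break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "file") offset <- as.integer(strsplit(val, "\\s+")[[1]][2])
      if (key == "datatype") datatype <- val
    }
  }
  if (is.null(offset)) stop("TCK header lacks a 'file' entry", call. = FALSE)
  if (!identical(datatype, "Float32LE")) {
    stop("unsupported TCK datatype: ", datatype, call. = FALSE)
  }
  n_float <- floor((length(raw) - offset) / 4)
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric", n = n_float,
                  size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  sl <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur)) sl[[length(sl) + 1]] <- cur
      cur <- NULL
    } else {
      cur <- rbind(cur, p)
    }
  }
  if (!is.null(cur)) sl[[length(sl) + 1]] <- cur
  sl <- lapply(sl, function(s) {
    dimnames(s) <- NULL
    s
  })
  tractogram(sl, subject_id = subject_id, space_tag = space_tag,
             max_length_mm = max_length_mm)
}

#' Write a tractogram to an MRtrix track (TCK) file
#'
#' @param tract A [tractogram()].
#' @param path Output TCK path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tract, path) {
  header_body <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    sprintf("count: %d\n", length(tract$streamlines))
  )
  # the 'file' line references the byte offset of the binary section,
  # which depends on the header length including that very line; fix by
  # iterating once with a generous width
  make_header <- function(off) paste0(header_body,
                                      sprintf("file: . %d\n", off), "END\n")
  off <- nchar(make_header(0), type = "bytes")
  off <- nchar(make_header(off), type = "bytes")
  header <- make_header(off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}
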