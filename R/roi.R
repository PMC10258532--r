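#' Construct a set of spherical regions of interest
#'
#' An `roi_set` is an ordered table of spherical ROIs in a common millimetre
#' coordinate space. The row order is fixed and defines the row/column order of
#' every distance and connectivity matrix derived from the set.
#'
#' @param id Character vector of unique ROI identifiers.
#' @param x,y,z Numeric vectors of sphere centres in mm (template space).
#' @param radius Numeric vector (or scalar, recycled) of sphere radii in mm;
#'   must be strictly positive.
#' @param label Optional character vector of free-text labels.
#' @param space_tag Name of the coordinate space the centres live in
#'   (e.g. `"MNI152"`). Sets with different tags cannot be mixed.
#'
#' @return A data frame of class `roi_set` with columns `id`, `x`, `y`, `z`,
#'   `radius`, `label` and attribute `space_tag`.
#'
#' @details Overlapping spheres are permitted (user-supplied ROI sets may
#'   overlap) but a message is emitted, since overlapping capture zones make
#'   endpoint assignment depend on the tie-breaking rule.
#'
#' @examples
#' rois <- roi_set(c("a", "b"), x = c(0, 30), y = 0, z = 0, radius = 8)
#' distance_matrix(rois)
#' @export
roi_set <- function(id, x, y, z, radius = 8, label = NA_character_,
                    space_tag = "MNI152") {
  id <- as.character(id)
  n <- length(id)
  df <- data.frame(
    id = id,
    x = as.numeric(rep_len(x, n)),
    y = as.numeric(rep_len(y, n)),
    z = as.numeric(rep_len(z, n)),
    radius = as.numeric(rep_len(radius, n)),
    label = as.character(rep_len(label, n)),
    stringsAsFactors = FALSE
  )
  validate_roi_set(df)
  attr(df, "space_tag") <- space_tag
  class(df) <- c("roi_set", "data.frame")
  df
}

validate_roi_set <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("ROI ids must be unique; duplicated: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  centres <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(centres))) stop("ROI centres must be finite", call. = FALSE)
  if (any(!is.finite(df$radius)) || any(df$radius <= 0)) {
    stop("ROI radii must be finite and > 0", call. = FALSE)
  }
  if (nrow(df) >= 2) {
    d <- as.matrix(stats::dist(centres))
    rr <- outer(df$radius, df$radius, "+")
    overlap <- d < rr & upper.tri(d)
    if (any(overlap)) {
      message(sum(overlap), " ROI pair(s) have overlapping spheres")
    }
  }
  invisible(df)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs in space '%s'\n", nrow(x), roi_space(x)))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

roi_space <- function(rois) attr(rois, "space_tag") %||% "unknown"

roi_centres <- function(rois) {
  m <- as.matrix(rois[, c("x", "y", "z")])
  rownames(m) <- rois$id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a lattice of spherical ROIs covering a mask or bounding box
#'
#' Places ROI centres on a regular cubic lattice of the given spacing and keeps
#' those falling inside the supplied region. The region may be a simple
#' axis-aligned bounding box in mm, or a binary NIfTI volume (anything
#' [RNifti::asNifti()] accepts), in which case a lattice point is kept when the
#' voxel containing it is non-zero. The ROI count is emergent from the region
#' and spacing; construction is fully deterministic.
#'
#' @param region Either a 2 x 3 numeric matrix `rbind(lower, upper)` of box
#'   corners in mm, or a binary volume with a NIfTI affine.
#' @param radius Sphere radius in mm (> 0). Default 8 mm.
#' @param spacing Lattice spacing in mm (> 0). The default, `2 * radius`,
#'   yields touching, non-overlapping spheres.
#' @param space_tag Coordinate-space tag for the resulting set.
#'
#' @return An [roi_set()]. Ids are derived from the lattice indices
#'   (`gXX.YY.ZZ`), so the same region and spacing always produce the same set.
#'
#' @examples
#' box <- rbind(c(0, 0, 0), c(40, 40, 40))
#' nrow(make_roi_grid(box, radius = 8, spacing = 20)) # 3 x 3 x 3 = 27
#' @export
make_roi_grid <- function(region, radius = 8, spacing = 2 * radius,
                          space_tag = "MNI152") {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)

  if (is.matrix(region) && identical(dim(region), c(2L, 3L))) {
    lo <- region[1, ]; hi <- region[2, ]
    if (any(hi < lo)) stop("box upper corner below lower corner", call. = FALSE)
    axes <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
    keep_fun <- function(pts) rep(TRUE, nrow(pts))
  } else {
    img <- RNifti::asNifti(region)
    arr <- as.array(img)
    if (length(dim(arr)) != 3) stop("mask must be a 3D volume", call. = FALSE)
    xf <- RNifti::xform(img)
    # world-space bounding box of all voxel centres (0-based indices)
    dims <- dim(arr)
    corners <- as.matrix(expand.grid(
      c(0, dims[1] - 1), c(0, dims[2] - 1), c(0, dims[3] - 1)))
    wc <- voxel_to_world(corners, xf)
    lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
    axes <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
    keep_fun <- function(pts) {
      vox <- round(world_to_voxel(pts, xf))
      inside <- vox[, 1] >= 0 & vox[, 1] < dims[1] &
        vox[, 2] >= 0 & vox[, 2] < dims[2] &
        vox[, 3] >= 0 & vox[, 3] < dims[3]
      keep <- rep(FALSE, nrow(pts))
      idx <- vox[inside, , drop = FALSE] + 1L
      keep[inside] <- arr[idx] != 0
      keep
    }
  }

  grid <- expand.grid(ix = seq_along(axes[[1]]),
                      iy = seq_along(axes[[2]]),
                      iz = seq_along(axes[[3]]))
  pts <- cbind(axes[[1]][grid$ix], axes[[2]][grid$iy], axes[[3]][grid$iz])
  keep <- keep_fun(pts)
  if (!any(keep)) stop("region contains no lattice points (empty mask?)",
                       call. = FALSE)
  grid <- grid[keep, , drop = FALSE]
  pts <- pts[keep, , drop = FALSE]
  ids <- sprintf("g%02d.%02d.%02d", grid$ix, grid$iy, grid$iz)
  suppressMessages(
    roi_set(ids, pts[, 1], pts[, 2], pts[, 3], radius = radius,
            space_tag = space_tag)
  )
}

# affine helpers: NIfTI xforms map 0-based voxel indices to world mm
voxel_to_world <- function(vox, xf) {
  vox <- cbind(as.matrix(vox), 1)
  t(xf %*% t(vox))[, 1:3, drop = FALSE]
}

world_to_voxel <- function(world, xf) {
  inv <- solve(xf)
  world <- cbind(as.matrix(world), 1)
  t(inv %*% t(world))[, 1:3, drop = FALSE]
}

#' Restrict an ROI set to spheres touching an interface mask
#'
#' Tractography endpoints are only anatomically meaningful near the grey/white
#' matter interface, so grid ROIs lying entirely inside grey or white matter
#' are dropped: an ROI is kept when at least one non-zero voxel centre of the
#' interface mask lies within its sphere.
#'
#' @param rois An [roi_set()].
#' @param interface_mask A binary volume with a NIfTI affine, in the same
#'   space as `rois`.
#'
#' @return The surviving subset of `rois` (possibly empty), ids preserved.
#' @export
restrict_to_interface <- function(rois, interface_mask) {
  img <- RNifti::asNifti(interface_mask)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("mask must be a 3D volume", call. = FALSE)
  on <- which(arr != 0, arr.ind = TRUE) - 1  # 0-based voxel indices
  if (nrow(on) == 0) {
    out <- rois[integer(0), , drop = FALSE]
    attr(out, "space_tag") <- roi_space(rois)
    class(out) <- c("roi_set", "data.frame")
    return(out)
  }
  vox_world <- voxel_to_world(on, RNifti::xform(img))
  centres <- roi_centres(rois)
  keep <- vapply(seq_len(nrow(rois)), function(i) {
    d2 <- colSums((t(vox_world) - centres[i, ])^2)
    any(d2 <= rois$radius[i]^2)
  }, logical(1))
  out <- rois[keep, , drop = FALSE]
  attr(out, "space_tag") <- roi_space(rois)
  class(out) <- c("roi_set", "data.frame")
  out
}
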