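#' Canonical 3D image volume
#'
#' The unit every pipeline stage consumes and produces: a 3D voxel grid with
#' physical spacing and explicit anatomical axis labels. The canonical
#' in-memory axis order is (sagittal index, coronal index, axial index), i.e.
#' dimension 1 walks left-right, dimension 2 walks anterior-posterior (the
#' coronal stacking direction) and dimension 3 walks superior-inferior.
#' Downstream code addresses axes by anatomical label, never by raw position.
#' A coronal slice is `voxels[, k, ]`; its in-plane spacing is
#' `spacing_inplane = c(row mm, col mm)` (rows = sagittal, cols = axial) and
#' consecutive slices are `slice_thickness` mm apart (zero slice gap assumed;
#' a nonzero gap found in metadata is warned about and the spacing between
#' slices is used for volumetry instead).
#'
#' The grid is 0-based with voxel centres at integer coordinates, so a voxel's
#' volume is exactly `spacing_inplane[1] * spacing_inplane[2] *
#' slice_thickness` mm^3 and volumetry reduces to the area-times-thickness sum.
#'
#' @param voxels 3D numeric array in canonical (sagittal, coronal, axial) order.
#' @param spacing_inplane numeric length-2, in-plane spacing of a coronal slice
#'   in mm (row = sagittal, col = axial); strictly positive.
#' @param slice_thickness coronal slice thickness in mm; strictly positive.
#' @param axis_labels character length-3 naming the anatomical direction each
#'   array dimension indexes; canonical order is
#'   `c("sagittal", "coronal", "axial")`.
#' @param source_id free-text provenance tag linking masks back to volumes.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_inplane, slice_thickness,
                         axis_labels = c("sagittal", "coronal", "axial"),
                         source_id = "unknown") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all grid dimensions must be >= 1")
  spacing_inplane <- as.numeric(spacing_inplane)
  if (length(spacing_inplane) != 2L || any(!is.finite(spacing_inplane)) ||
      any(spacing_inplane <= 0))
    stop("`spacing_inplane` must be two strictly positive numbers (mm)")
  slice_thickness <- as.numeric(slice_thickness)
  if (length(slice_thickness) != 1L || !is.finite(slice_thickness) ||
      slice_thickness <= 0)
    stop("`slice_thickness` must be a single strictly positive number (mm)")
  axis_labels <- as.character(axis_labels)
  if (length(axis_labels) != 3L ||
      !setequal(axis_labels, c("sagittal", "coronal", "axial")))
    stop("`axis_labels` must be a permutation of sagittal/coronal/axial")
  structure(
    list(voxels = voxels,
         spacing_inplane = spacing_inplane,
         slice_thickness = slice_thickness,
         axis_labels = axis_labels,
         source_id = as.character(source_id)[1]),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_volume> %d x %d x %d (%s), in-plane %.3g x %.3g mm, thickness %.3g mm, source '%s'\n",
    d[1], d[2], d[3], paste(x$axis_labels, collapse = " x "),
    x$spacing_inplane[1], x$spacing_inplane[2], x$slice_thickness, x$source_id))
  invisible(x)
}

#' @rdname image_volume
#' @param x object to test.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

# index of the array dimension holding the given anatomical stack
axis_dim <- function(vol, label) match(label, vol$axis_labels)

#' Number of coronal slices in a volume
#' @param vol an `image_volume`.
#' @return integer count of coronal slices.
#' @export
n_coronal <- function(vol) dim(vol$voxels)[axis_dim(vol, "coronal")]

#' Extract one coronal slice as a matrix
#'
#' Rows index the sagittal (left-right) direction, columns the axial
#' (superior-inferior) direction.
#'
#' @param vol an `image_volume`.
#' @param k 1-based coronal slice index.
#' @return numeric matrix.
#' @export
coronal_slice <- function(vol, k) {
  stopifnot(k >= 1, k <= n_coronal(vol))
  vol$voxels[, k, , drop = TRUE]
}

set_coronal_slice <- function(vol, k, slice) {
  vol$voxels[, k, ] <- slice
  vol
}

#' Binary kidney mask
#'
#' A binary 3D grid congruent with its source [image_volume()], labelled with
#' the kidney side.
#'
#' @param voxels 3D array of 0/1 (or logical) values, same shape as the
#'   linked volume.
#' @param side `"left"` or `"right"`.
#' @param grid_link `source_id` of the volume the mask lives on.
#' @param spacing_inplane,slice_thickness grid geometry, copied from the
#'   source volume so a mask is self-contained for volumetry and file output.
#' @return An object of class `kidney_mask`.
#' @export
kidney_mask <- function(voxels, side = c("left", "right"),
                        grid_link = "unknown",
                        spacing_inplane = c(1, 1), slice_thickness = 1) {
  side <- match.arg(side)
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim = dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1))) stop("mask values must be strictly binary (0/1)")
  structure(
    list(voxels = voxels, side = side, grid_link = as.character(grid_link)[1],
         spacing_inplane = as.numeric(spacing_inplane),
         slice_thickness = as.numeric(slice_thickness)),
    class = "kidney_mask")
}

#' @rdname kidney_mask
#' @param x object to test.
#' @export
is_kidney_mask <- function(x) inherits(x, "kidney_mask")

#' @export
print.kidney_mask <- function(x, ...) {
  cat(sprintf("<kidney_mask> %s kidney, %s voxels set, grid '%s'\n",
              x$side, format(sum(x$voxels)), x$grid_link))
  invisible(x)
}

# mask congruence check used by volumetry and Dice
check_congruent <- function(a, b) {
  da <- dim(a$voxels); db <- dim(b$voxels)
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}
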