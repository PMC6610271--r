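# The two estimating equations the segmentation pipeline is compared
# against: the ellipsoid formula from three caliper measurements, and the
# mid-slice estimate from one traced mid-slice area.

#' Ellipsoid kidney volume estimate
#'
#' `pi/6 * length * width * depth`, converted to ml. The formula assumes the
#' near-ellipsoidal kidney shape of typical (Mayo class 1) disease; for
#' atypical (class 2) morphology it is unreliable and the call refuses with
#' an error rather than returning a misleading number.
#'
#' @param length_mm,width_mm,depth_mm maximal kidney dimensions, mm.
#' @param atypical set `TRUE` for class 2 (atypical) morphology.
#' @return volume in ml.
#' @export
ellipsoid_volume <- function(length_mm, width_mm, depth_mm, atypical = FALSE) {
  if (isTRUE(atypical))
    stop(paste("the ellipsoid formula is not reliable for atypical (class 2)",
               "morphology; these kidneys are not ellipsoidal"))
  if (any(c(length_mm, width_mm, depth_mm) <= 0))
    stop("all three measurements must be > 0 mm")
  pi / 6 * length_mm * width_mm * depth_mm / 1000
}

#' Mid-slice kidney volume estimate
#'
#' `coefficient * mid-slice area * number of kidney-bearing slices * slice
#' thickness`, in ml. The default coefficient 0.624 is the published
#' single-mid-slice correction factor; at coefficient 1 the estimate is exact
#' for a constant-cross-section (slab) kidney.
#'
#' @param mid_slice_area_mm2 traced kidney area on the mid-coronal slice.
#' @param n_slices number of slices containing kidney.
#' @param slice_thickness_mm slice thickness, mm.
#' @param coefficient dimensionless correction factor.
#' @return volume in ml.
#' @export
midslice_volume <- function(mid_slice_area_mm2, n_slices, slice_thickness_mm,
                            coefficient = 0.624) {
  if (mid_slice_area_mm2 <= 0) stop("mid-slice area must be > 0")
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (slice_thickness_mm <= 0 || coefficient <= 0)
    stop("thickness and coefficient must be > 0")
  coefficient * mid_slice_area_mm2 * n_slices * slice_thickness_mm / 1000
}

# measure the mid-slice inputs and axis-aligned extents from a ground-truth
# or segmented mask, for estimator comparisons on phantoms
mask_midslice_input <- function(mask) {
  per_slice <- apply(mask$voxels, 2, sum)
  occupied <- which(per_slice > 0)
  if (length(occupied) == 0) stop("empty mask")
  mid <- occupied[(length(occupied) + 1L) %/% 2L]
  area <- per_slice[mid] * mask$spacing_inplane[1] * mask$spacing_inplane[2]
  list(mid_slice_area_mm2 = area, n_slices = length(occupied),
       slice_thickness_mm = mask$slice_thickness, mid_slice = mid)
}

mask_extents_mm <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  sp <- c(mask$spacing_inplane[1], mask$slice_thickness, mask$spacing_inplane[2])
  ext <- unname((apply(idx, 2, max) - apply(idx, 2, min) + 1) * sp)
  # length = largest extent, depth = anterior-posterior, width = the third
  c(length_mm = max(ext[c(1, 3)]), width_mm = min(ext[c(1, 3)]),
    depth_mm = ext[2])
}
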