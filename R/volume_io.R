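# NIfTI I/O goes through RNifti; volumes are permuted to the canonical
# (sagittal, coronal, axial) axis order at read time from the header's
# orientation codes, so downstream code can address axes anatomically.

orientation_to_labels <- function(code) {
  lut <- c(R = "sagittal", L = "sagittal", A = "coronal", P = "coronal",
           S = "axial", I = "axial")
  letters3 <- strsplit(code, "")[[1]]
  labels <- unname(lut[letters3])
  if (length(labels) != 3 || anyNA(labels) ||
      length(unique(labels)) != 3)
    stop(sprintf("cannot resolve anatomical axes from orientation '%s'", code))
  labels
}

#' Read a NIfTI-1 volume
#'
#' Spacing is taken from the header's pixdims and the anatomical axis of each
#' array dimension from the qform/sform orientation; the volume is permuted to
#' canonical (sagittal, coronal, axial) order. When the file carries no usable
#' orientation the canonical order is assumed with a warning — orientation is
#' surfaced, never silently invented.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return an [image_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("corrupt or unreadable NIfTI '%s': %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D payload, got %dD", length(dim(arr))))
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive pixdim in NIfTI header")
  code <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.na(code) || !nzchar(code)) {
    warning("NIfTI file carries no orientation; assuming canonical (sagittal, coronal, axial)")
    labels <- c("sagittal", "coronal", "axial")
  } else {
    labels <- orientation_to_labels(code)
  }
  perm <- match(c("sagittal", "coronal", "axial"), labels)
  arr <- aperm(arr, perm)
  pd <- pd[perm]
  image_volume(arr, spacing_inplane = c(pd[1], pd[3]), slice_thickness = pd[2],
               source_id = basename(path))
}

#' Write an image volume to NIfTI-1
#'
#' The canonical axis order is encoded with a diagonal sform (dimension 1
#' left-right, 2 anterior-posterior, 3 superior-inferior), so
#' [read_nifti()] round-trips voxels, spacing and axis labels exactly.
#'
#' @param vol an [image_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  perm <- match(vol$axis_labels, c("sagittal", "coronal", "axial"))
  arr <- aperm(vol$voxels, order(perm))  # ensure canonical order on disk
  pd <- c(vol$spacing_inplane[1], vol$slice_thickness, vol$spacing_inplane[2])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  xf <- diag(c(pd, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a kidney mask to NIfTI with a JSON sidecar
#'
#' The mask is written as a {0,1} NIfTI volume on its source grid geometry;
#' side, grid link, segmentation method and parameters go to `<path>.json`.
#'
#' @param mask a [kidney_mask()].
#' @param path output NIfTI path.
#' @param method free-text method tag recorded in the sidecar.
#' @param params optional named list of parameters recorded in the sidecar.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path, method = "levelset", params = NULL) {
  stopifnot(is_kidney_mask(mask))
  vol <- image_volume(mask$voxels, mask$spacing_inplane, mask$slice_thickness,
                      source_id = mask$grid_link)
  write_nifti_volume(vol, path)
  sidecar <- list(side = mask$side, grid_link = mask$grid_link, method = method)
  if (!is.null(params)) sidecar$params <- params
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a kidney mask written by [write_mask()]
#'
#' @param path the NIfTI path given to [write_mask()].
#' @return a [kidney_mask()] with side and grid link restored from the sidecar.
#' @export
read_mask <- function(path) {
  vol <- read_nifti(path)
  sidecar_path <- paste0(path, ".json")
  side <- "left"; link <- vol$source_id
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (!is.null(sc$side)) side <- sc$side
    if (!is.null(sc$grid_link)) link <- sc$grid_link
  }
  kidney_mask(array(as.integer(vol$voxels != 0), dim = dim(vol$voxels)),
              side = side, grid_link = link,
              spacing_inplane = vol$spacing_inplane,
              slice_thickness = vol$slice_thickness)
}
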