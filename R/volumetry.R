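#' Kidney volume from a binary mask
#'
#' Per coronal slice, area = voxel count times in-plane voxel area; volume is
#' the sum of area times slice thickness, returned in ml (1 ml = 1000 mm^3).
#' With zero slice gap this equals voxel count times voxel volume.
#'
#' @param mask a [kidney_mask()].
#' @param vol optional [image_volume()] the mask must be congruent with; when
#'   supplied its geometry is used and the grids are checked.
#' @return volume in ml.
#' @export
mask_volume <- function(mask, vol = NULL) {
  stopifnot(is_kidney_mask(mask))
  if (!is.null(vol)) {
    check_congruent(mask, vol)
    sp <- vol$spacing_inplane; th <- vol$slice_thickness
  } else {
    sp <- mask$spacing_inplane; th <- mask$slice_thickness
  }
  sum(mask$voxels) * sp[1] * sp[2] * th / 1000
}

#' Per-patient volume report
#'
#' Records per-side kidney volumes, their sum (TKV) and, when height is
#' supplied, height-adjusted TKV, together with method provenance.
#'
#' @param right_kv_ml,left_kv_ml per-kidney volumes in ml (>= 0).
#' @param method one of `"manual"`, `"levelset"`, `"ellipsoid"`, `"midslice"`.
#' @param height_m optional patient height in metres.
#' @param params_digest free-text parameter provenance.
#' @return An object of class `volume_report`.
#' @export
volume_report <- function(right_kv_ml, left_kv_ml,
                          method = c("levelset", "manual", "ellipsoid", "midslice"),
                          height_m = NULL, params_digest = "") {
  method <- match.arg(method)
  if (right_kv_ml < 0 || left_kv_ml < 0) stop("kidney volumes must be >= 0")
  tkv <- right_kv_ml + left_kv_ml
  htkv <- if (!is.null(height_m)) height_adjust(tkv, height_m) else NA_real_
  structure(list(right_kv_ml = right_kv_ml, left_kv_ml = left_kv_ml,
                 tkv_ml = tkv, htkv_ml_per_m = htkv, method = method,
                 params_digest = params_digest),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> [%s] right %.1f ml, left %.1f ml, TKV %.1f ml%s\n",
              x$method, x$right_kv_ml, x$left_kv_ml, x$tkv_ml,
              if (is.na(x$htkv_ml_per_m)) ""
              else sprintf(", HtTKV %.1f ml/m", x$htkv_ml_per_m)))
  invisible(x)
}

#' Total kidney volume from the two sides
#'
#' TKV is the sum of the right and left kidney volumes; the sides are kept
#' separately in the report so side-specific errors stay identifiable.
#'
#' @inheritParams volume_report
#' @return a [volume_report()].
#' @export
total_kidney_volume <- function(right_kv_ml, left_kv_ml, method = "levelset",
                                height_m = NULL, params_digest = "") {
  volume_report(right_kv_ml, left_kv_ml, method = method,
                height_m = height_m, params_digest = params_digest)
}

#' Height-adjusted total kidney volume
#'
#' @param tkv_ml total kidney volume in ml.
#' @param height_m patient height in metres (> 0).
#' @return HtTKV in ml per metre.
#' @export
height_adjust <- function(tkv_ml, height_m) {
  if (!is.numeric(height_m) || height_m <= 0) stop("height must be > 0 metres")
  tkv_ml / height_m
}

#' Serialise a volume report
#'
#' @param report a [volume_report()].
#' @param path optional path; `.json` extension writes JSON, otherwise a
#'   one-row CSV.
#' @return the report as a one-row data frame (invisibly when writing).
#' @export
report_to_table <- function(report, path = NULL) {
  df <- data.frame(right_kv_ml = report$right_kv_ml,
                   left_kv_ml = report$left_kv_ml,
                   tkv_ml = report$tkv_ml,
                   htkv_ml_per_m = report$htkv_ml_per_m,
                   method = report$method,
                   params_digest = report$params_digest,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    if (grepl("\\.json$", path))
      jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    else utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
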