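# End-to-end workflow: slice selection from a sagittal landmark,
# pre-processing, ROI cropping, per-kidney level-set segmentation, and
# volumetry — plus helpers that derive the user-interaction inputs
# (landmark, seed contour, crop rectangle) analytically from a phantom's
# ground truth, standing in for the interactive picks in batch runs.

#' Inputs one kidney needs for a pipeline run
#'
#' @param landmark a [sagittal_landmark()].
#' @param seed a [seed_contour()] in full-volume coordinates.
#' @param rect crop rectangle `c(row_min, row_max, col_min, col_max)` in
#'   coronal-slice coordinates.
#' @param side `"left"` or `"right"`.
#' @return a list bundling the inputs.
#' @export
kidney_inputs <- function(landmark, seed, rect, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(landmark, "sagittal_landmark"), inherits(seed, "seed_contour"))
  list(landmark = landmark, seed = seed, rect = as.integer(rect), side = side)
}

#' Run the full segmentation pipeline on one volume
#'
#' Per kidney: the sagittal landmark selects the coronal slice range, the
#' enabled pre-processing stages run over that range (motion, then bias,
#' then inter-slice normalisation), the ROI is cropped, the level set is
#' seeded on the mid-coronal slice and propagated through the stack, and the
#' resulting mask is mapped back to the full grid. Kidneys are processed
#' independently so side-specific errors stay identifiable.
#'
#' @param vol an [image_volume()].
#' @param kidneys list of [kidney_inputs()] (typically right and left).
#' @param params a [levelset_params()].
#' @param margin slice-range dilation passed to [select_coronal_slices()].
#' @param do_motion,do_bias,do_interslice pre-processing toggles.
#' @param height_m optional patient height for HtTKV.
#' @return list with `report` (a [volume_report()]), `masks` (per-kidney,
#'   full grid), and `ranges` (per-kidney slice ranges).
#' @export
tkv_pipeline <- function(vol, kidneys, params = levelset_params(),
                         margin = 2L, do_motion = FALSE, do_bias = FALSE,
                         do_interslice = TRUE, height_m = NULL) {
  stopifnot(is_image_volume(vol), length(kidneys) >= 1)
  masks <- list(); ranges <- list()
  kv <- c(right = 0, left = 0)
  for (ki in kidneys) {
    rng <- select_coronal_slices(vol, ki$landmark, margin = margin)
    work <- vol
    if (do_motion) work <- correct_motion(work, rng)$vol
    if (do_bias) {
      for (k in rng[1]:rng[2]) {
        sl <- coronal_slice(work, k)
        work <- set_coronal_slice(work, k, correct_bias_field(sl)$corrected)
      }
    }
    if (do_interslice) work <- normalize_interslice(work, rng)$vol
    cropped <- crop_roi(work, ki$rect, rng)
    seed_local <- seed_contour(
      ki$seed$slice_index - (rng[1] - 1L),
      cbind(ki$seed$points[, 1] - (ki$rect[1] - 1L),
            ki$seed$points[, 2] - (ki$rect[3] - 1L)))
    m <- segment_kidney(cropped, seed_local, params, side = ki$side)
    full <- uncrop_mask(m, cropped)
    masks[[ki$side]] <- full
    ranges[[ki$side]] <- rng
    kv[ki$side] <- mask_volume(full, vol)
  }
  report <- total_kidney_volume(kv[["right"]], kv[["left"]],
                                method = "levelset", height_m = height_m,
                                params_digest = paste0(
                                  "alpha=", params$alpha, ";beta=", params$beta,
                                  ";mu=", params$mu, ";iter=", params$iterations))
  list(report = report, masks = masks, ranges = ranges)
}

# mm position -> 1-based voxel index on the phantom grid
phantom_mm_to_voxel <- function(ph, p_mm) {
  sp <- c(ph$spec$spacing_inplane[1], ph$spec$slice_thickness,
          ph$spec$spacing_inplane[2])
  (p_mm - ph$origin_mm) / sp + 1
}

#' Derive pipeline inputs for one phantom kidney from its ground truth
#'
#' Builds the sagittal landmark (the kidney's anterior-posterior poles on the
#' sagittal slice through its centre), an elliptical seed contour on the
#' mid-coronal slice scaled to `seed_scale` of the true cross-section, and a
#' crop rectangle around the kidney — the batch analogue of the interactive
#' picks.
#'
#' @param ph result of [phantom_generate()].
#' @param kidney_index which kidney in the spec.
#' @param seed_scale fraction of the true boundary radius for the seed.
#' @param seed_offset_vox radial offset in voxels added after scaling
#'   (positive = outward); lets seed-placement robustness be probed directly.
#' @param margin_vox in-plane crop margin in voxels.
#' @param n_vertices seed polygon vertex count.
#' @return a [kidney_inputs()] list.
#' @export
phantom_case_inputs <- function(ph, kidney_index = 1L, seed_scale = 0.9,
                                seed_offset_vox = 0, margin_vox = 8L,
                                n_vertices = 48L) {
  kd <- ph$spec$kidneys[[kidney_index]]
  sp_in <- ph$spec$spacing_inplane
  d <- dim(ph$vol$voxels)
  cv <- phantom_mm_to_voxel(ph, kd$centre)

  sag_idx <- as.integer(round(cv[1]))
  ap_lo <- phantom_mm_to_voxel(ph, kd$centre - c(0, kd$semiaxes[2], 0))[2]
  ap_hi <- phantom_mm_to_voxel(ph, kd$centre + c(0, kd$semiaxes[2], 0))[2]
  landmark <- sagittal_landmark(sag_idx,
                                rbind(c(ap_lo, cv[3]), c(ap_hi, cv[3])))

  ang <- if (is.null(kd$angle_deg)) 0 else kd$angle_deg
  th <- ang * pi / 180
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  u <- kd$semiaxes[1] * cos(t); w <- kd$semiaxes[3] * sin(t)
  scl <- seed_scale + seed_offset_vox * mean(sp_in) /
    sqrt(kd$semiaxes[1] * kd$semiaxes[3])
  u <- u * scl; w <- w * scl
  x_mm <- kd$centre[1] + cos(th) * u - sin(th) * w
  z_mm <- kd$centre[3] + sin(th) * u + cos(th) * w
  rows <- (x_mm - ph$origin_mm[1]) / sp_in[1] + 1
  cols <- (z_mm - ph$origin_mm[3]) / sp_in[2] + 1
  seed <- seed_contour(as.integer(round(cv[2])), cbind(rows, cols))

  ext <- max(kd$semiaxes[c(1, 3)])
  r1 <- max(1L, floor((kd$centre[1] - ext - ph$origin_mm[1]) / sp_in[1] + 1) - margin_vox)
  r2 <- min(d[1], ceiling((kd$centre[1] + ext - ph$origin_mm[1]) / sp_in[1] + 1) + margin_vox)
  c1 <- max(1L, floor((kd$centre[3] - ext - ph$origin_mm[3]) / sp_in[2] + 1) - margin_vox)
  c2 <- min(d[3], ceiling((kd$centre[3] + ext - ph$origin_mm[3]) / sp_in[2] + 1) + margin_vox)

  side <- if (is.null(kd$side)) c("right", "left")[(kidney_index - 1L) %% 2L + 1L]
          else kd$side
  kidney_inputs(landmark, seed, c(r1, r2, c1, c2), side = side)
}

#' Segment a whole phantom case and score it against ground truth
#'
#' Runs [tkv_pipeline()] on the degraded phantom volume with ground-truth-
#' derived inputs and reports measured volumes, analytic truth, percentage
#' TKV error and per-kidney Dice coefficients.
#'
#' @param ph result of [phantom_generate()].
#' @param params a [levelset_params()].
#' @param seed_scale passed to [phantom_case_inputs()].
#' @param ... passed to [tkv_pipeline()] (pre-processing toggles etc.).
#' @return list with `report`, `masks`, `dsc` (per kidney), `tkv_true_ml`,
#'   `tkv_measured_ml`, `tkv_error_pct`, `kv_true_ml`, `kv_measured_ml`.
#' @export
run_phantom_case <- function(ph, params = levelset_params(), seed_scale = 0.9,
                             ...) {
  nk <- length(ph$spec$kidneys)
  kidneys <- lapply(seq_len(nk), function(i)
    phantom_case_inputs(ph, i, seed_scale = seed_scale))
  res <- tkv_pipeline(ph$vol, kidneys, params = params, ...)
  dsc <- vapply(seq_len(nk), function(i) {
    side <- kidneys[[i]]$side
    dice(res$masks[[side]], ph$masks[[i]])
  }, numeric(1))
  names(dsc) <- vapply(kidneys, `[[`, character(1), "side")
  kv_meas <- vapply(seq_len(nk), function(i)
    mask_volume(res$masks[[kidneys[[i]]$side]]), numeric(1))
  tkv_true <- sum(ph$analytic_ml)
  tkv_meas <- res$report$tkv_ml
  list(report = res$report, masks = res$masks, dsc = dsc,
       tkv_true_ml = tkv_true, tkv_measured_ml = tkv_meas,
       tkv_error_pct = 100 * (tkv_meas - tkv_true) / tkv_true,
       kv_true_ml = ph$analytic_ml, kv_measured_ml = kv_meas)
}
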