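test_that("sagittal landmark selects and clips the coronal slice range", {
  ph <- fx_phantom_clean()
  kd <- ph$spec$kidneys[[1]]
  ki <- phantom_case_inputs(ph, 1)
  rng <- select_coronal_slices(ph$vol, ki$landmark, margin = 2L)
  occ <- which(apply(ph$masks[[1]]$voxels, 2, sum) > 0)
  # the landmark spans the kidney's anterior-posterior poles, so the range
  # dilated by the margin must contain every occupied slice
  expect_lte(rng[1], min(occ))
  expect_gte(rng[2], max(occ))
  expect_gte(rng[1], 1)
  expect_lte(rng[2], n_coronal(ph$vol))
  # margin 0 with points one slice apart maps those coronal positions exactly
  lm <- sagittal_landmark(5, rbind(c(7, 10), c(8, 12)))
  expect_equal(unname(select_coronal_slices(ph$vol, lm, margin = 0L)), c(7L, 8L))
  expect_error(sagittal_landmark(5, rbind(c(7, 10), c(7, 10))), "degenerate")
  bad <- sagittal_landmark(5, rbind(c(1e5, 10), c(8, 12)))
  expect_error(select_coronal_slices(ph$vol, bad), "outside")
})

test_that("motion correction recovers injected rigid motion", {
  ph <- fixture("motion", function()
    phantom_generate(phantom_two_kidney_spec(
      tkv_ml = 800, seed = 11, noise_sd = 2,
      motion_max_translation_voxels = 3, motion_max_rotation_deg = 2)))
  occ <- occupied_slices(ph, 500)
  rng <- c(min(occ), max(occ))
  cm <- correct_motion(ph$vol, rng, reference = ph$reference_slice)
  inj <- ph$motion; rec <- cm$motion
  for (k in rng[1]:rng[2]) {
    want <- tkvtools:::invert_rigid2d(inj$angle_deg[k], inj$tx[k], inj$ty[k])
    i <- match(k, rec$slice)
    expect_lt(sqrt((rec$tx[i] - want["tx"])^2 + (rec$ty[i] - want["ty"])^2), 0.5)
    expect_lt(abs(rec$angle_deg[i] - want["angle_deg"]), 0.5)
  }
  # reference slice keeps the identity transform
  iref <- match(ph$reference_slice, rec$slice)
  expect_equal(unname(unlist(rec[iref, c("angle_deg", "tx", "ty")])), c(0, 0, 0))
})

test_that("motion-free volumes yield near-identity transforms", {
  ph <- fixture("motionfree", function()
    phantom_generate(phantom_two_kidney_spec(tkv_ml = 800, seed = 11,
                                             noise_sd = 2)))
  occ <- occupied_slices(ph, 500)
  cm <- correct_motion(ph$vol, c(min(occ), max(occ)))
  expect_lt(max(abs(c(cm$motion$tx, cm$motion$ty))), 0.5)
  expect_lt(max(abs(cm$motion$angle_deg)), 0.5)
})

test_that("recovered transforms preserve mask volume under round trip", {
  ph <- fixture("motion", function()
    phantom_generate(phantom_two_kidney_spec(
      tkv_ml = 800, seed = 11, noise_sd = 2,
      motion_max_translation_voxels = 3, motion_max_rotation_deg = 2)))
  occ <- occupied_slices(ph, 500)
  cm <- correct_motion(ph$vol, c(min(occ), max(occ)),
                       reference = ph$reference_slice)
  vx <- ph$masks[[1]]$voxels
  n0 <- sum(vx)
  for (k in min(occ):max(occ)) {
    i <- match(k, cm$motion$slice)
    p <- unlist(cm$motion[i, c("angle_deg", "tx", "ty")])
    fwd <- tkvtools:::apply_rigid2d(vx[, k, ], p[1], p[2], p[3])
    inv <- tkvtools:::invert_rigid2d(p[1], p[2], p[3])
    back <- tkvtools:::apply_rigid2d(fwd, inv[1], inv[2], inv[3])
    vx[, k, ] <- as.integer(back > 0.5)
  }
  expect_lt(abs(sum(vx) - n0) / n0, 0.01)
})

test_that("bias-field correction recovers an injected smooth field", {
  ph <- fixture("bias", function()
    phantom_generate(phantom_two_kidney_spec(
      tkv_ml = 800, seed = 12, noise_sd = 2, bias_amplitude = 0.3,
      texture_kidney = 0, texture_background = 0.1)))
  k <- ph$reference_slice
  sl <- coronal_slice(ph$vol, k)
  tissue <- (ph$masks[[1]]$voxels[, k, ] + ph$masks[[2]]$voxels[, k, ]) > 0
  bc <- correct_bias_field(sl)
  cov <- function(x) stats::sd(x) / mean(x)
  expect_lt(cov(bc$corrected[tissue]), 0.5 * cov(sl[tissue]))
  expect_gte(cor(as.vector(bc$field[tissue]),
                 as.vector(ph$bias_fields[[k]][tissue])), 0.9)
  expect_true(all(bc$field > 0))
  # mean intensity is preserved (unit-mean field)
  expect_equal(mean(bc$field), 1, tolerance = 1e-6)
})

test_that("bias correction leaves an unbiased slice nearly unchanged", {
  ph <- fixture("nobias", function()
    phantom_generate(phantom_two_kidney_spec(
      tkv_ml = 800, seed = 12, noise_sd = 2,
      texture_kidney = 0, texture_background = 0.1)))
  k <- ph$reference_slice
  bc <- correct_bias_field(coronal_slice(ph$vol, k))
  expect_lt(max(abs(bc$field - 1)), 0.05)
  expect_lt(bc$entropy["after"] - bc$entropy["before"], 0.02)
  # constant slice is returned untouched
  const <- correct_bias_field(matrix(7, 20, 20))
  expect_equal(const$corrected, matrix(7, 20, 20))
  expect_equal(const$field, matrix(1, 20, 20))
})

test_that("bias correction is idempotent within tolerance", {
  ph <- fixture("bias", function()
    phantom_generate(phantom_two_kidney_spec(
      tkv_ml = 800, seed = 12, noise_sd = 2, bias_amplitude = 0.3,
      texture_kidney = 0, texture_background = 0.1)))
  k <- ph$reference_slice
  sl <- coronal_slice(ph$vol, k)
  b1 <- correct_bias_field(sl)
  b2 <- correct_bias_field(b1$corrected)
  change1 <- sqrt(mean((b1$corrected - sl)^2))
  change2 <- sqrt(mean((b2$corrected - b1$corrected)^2))
  expect_lt(change2, 0.1 * change1)
})

test_that("inter-slice normalisation inverts injected gain drift", {
  ph <- fixture("gain", function()
    phantom_generate(phantom_two_kidney_spec(
      tkv_ml = 800, seed = 13, noise_sd = 2,
      interslice_gain_range = c(0.7, 1.3), body = FALSE)))
  occ <- occupied_slices(ph)
  nr <- suppressWarnings(normalize_interslice(ph$vol, c(min(occ), max(occ))))
  g <- nr$gains
  keep <- g$slice %in% occ
  ratio <- g$multiplier[keep] * ph$gains[occ]
  # recovered multipliers proportional to 1/g within 5%
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.05)
  expect_true(all(g$multiplier > 0))
  # across-slice SD of bright-tissue means drops by >= 80%
  bright_means <- function(v) vapply(occ, function(k) {
    sl <- coronal_slice(v, k)
    q <- stats::quantile(sl, 0.99, names = FALSE)
    mean(sl[sl > 0.5 * q])
  }, numeric(1))
  expect_lt(stats::sd(bright_means(nr$vol)), 0.2 * stats::sd(bright_means(ph$vol)))
})

test_that("normalisation of identical slices is the identity, and repeats are stable", {
  # a volume whose slices are identical copies
  sl <- matrix(10, 30, 30); sl[10:20, 10:20] <- 120
  vox <- array(0, c(30, 6, 30))
  for (k in 1:6) vox[, k, ] <- sl
  vol <- image_volume(vox, c(1, 1), 4)
  nr <- normalize_interslice(vol)
  expect_equal(nr$gains$multiplier, rep(1, 6), tolerance = 1e-10)
  # idempotency: second pass finds nothing to change
  nr2 <- normalize_interslice(nr$vol)
  expect_equal(nr2$gains$multiplier, rep(1, 6), tolerance = 1e-10)
})

test_that("crop and uncrop round-trip masks exactly", {
  ph <- fx_phantom_small()
  ki <- phantom_case_inputs(ph, 1)
  rng <- select_coronal_slices(ph$vol, ki$landmark)
  cropped <- crop_roi(ph$vol, ki$rect, rng)
  expect_equal(cropped$spacing_inplane, ph$vol$spacing_inplane)
  # full-extent crop is the identity
  d <- dim(ph$vol$voxels)
  full <- crop_roi(ph$vol, c(1, d[1], 1, d[3]), c(1, n_coronal(ph$vol)))
  expect_equal(full$voxels, ph$vol$voxels)
  # mask positions survive crop -> uncrop exactly
  sub <- ph$masks[[1]]$voxels[ki$rect[1]:ki$rect[2], rng[1]:rng[2],
                              ki$rect[3]:ki$rect[4], drop = FALSE]
  m <- kidney_mask(sub, side = "right",
                   spacing_inplane = ph$vol$spacing_inplane,
                   slice_thickness = ph$vol$slice_thickness)
  back <- uncrop_mask(m, cropped)
  expect_equal(back$voxels, ph$masks[[1]]$voxels, ignore_attr = TRUE)
  expect_error(crop_roi(ph$vol, c(5, 4, 1, 10)), "empty|malformed")
  expect_error(crop_roi(ph$vol, c(0, 4, 1, 10)), "outside")
})
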