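# Synthetic abdominal phantom: bright ellipsoidal kidneys with hyperintense
# internal cysts on a darker background, degraded (in order) by per-slice
# gain drift, smooth multiplicative intra-slice bias, small per-slice rigid
# motion and additive noise. Every degradation is returned alongside the
# clean geometry so the correction stages can be tested against exact truth.

#' Specify a synthetic polycystic-kidney phantom
#'
#' Geometry is given in mm in canonical (sagittal, coronal, axial) patient
#' coordinates. Each kidney is an ellipsoid (optionally tilted in the coronal
#' plane) whose analytic volume is known exactly; cysts are hyperintense
#' spheres placed fully inside the parenchyma. Intensities default to a
#' T2-like contrast on an arbitrary scale: background well below, parenchyma
#' well above, the segmentation's region threshold.
#'
#' @param kidneys list of kidneys, each a list with `centre` (mm, length 3 in
#'   canonical order), `semiaxes` (mm, length 3: left-right,
#'   anterior-posterior, superior-inferior), optional `angle_deg` (tilt about
#'   the anterior-posterior axis) and `side` ("left"/"right").
#' @param spacing_inplane in-plane spacing of a coronal slice, mm.
#' @param slice_thickness coronal slice thickness, mm.
#' @param shape grid dimensions; `NULL` sizes the grid to the kidneys plus
#'   `margin_mm`.
#' @param margin_mm background margin around the kidneys when `shape` is `NULL`.
#' @param kidney_intensity,background_intensity,cyst_intensity tissue levels.
#' @param n_cysts cysts per kidney.
#' @param cyst_radius_range radius range in mm (capped so cysts fit inside).
#' @param bias_amplitude fractional amplitude of the smooth multiplicative
#'   intra-slice bias field (0 disables).
#' @param interslice_gain_range range of the per-slice global gain multiplier
#'   (`c(1, 1)` disables).
#' @param motion_max_translation_voxels,motion_max_rotation_deg per-slice
#'   rigid motion bounds (0 disables).
#' @param noise_sd additive Gaussian noise SD.
#' @param texture_kidney,texture_background fractional amplitude of the
#'   smooth 3D anatomical texture (random superposed cosine waves with
#'   mm-scale correlation) modulating parenchyma and background. Real
#'   abdominal MRI is never piecewise constant; the shared structure between
#'   adjacent slices is what anchors inter-slice registration.
#' @param texture_wavelength_mm correlation wavelength range of the texture.
#' @param liver_abut add a bright liver-like slab abutting the right kidney,
#'   the classic low-contrast hard case.
#' @param body render the abdominal cross-section: moderate body interior
#'   with a bright subcutaneous fat ring and near-zero signal outside.
#'   Besides realism, the body outline shared by adjacent coronal slices is
#'   what anchors inter-slice motion correction, as in real scans.
#' @param body_intensity,fat_intensity,void_intensity tissue levels of body
#'   interior, fat ring and air.
#' @param fat_thickness_mm thickness of the fat ring.
#' @param seed integer fixing all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kidneys,
                         spacing_inplane = c(1.5, 1.5),
                         slice_thickness = 4,
                         shape = NULL,
                         margin_mm = 30,
                         kidney_intensity = 120,
                         background_intensity = 10,
                         cyst_intensity = 200,
                         n_cysts = 0,
                         cyst_radius_range = c(4, 12),
                         bias_amplitude = 0,
                         interslice_gain_range = c(1, 1),
                         motion_max_translation_voxels = 0,
                         motion_max_rotation_deg = 0,
                         noise_sd = 0,
                         texture_kidney = 0.05,
                         texture_background = 0.35,
                         texture_wavelength_mm = c(18, 40),
                         liver_abut = FALSE,
                         body = TRUE,
                         body_intensity = 15,
                         fat_intensity = 170,
                         void_intensity = 5,
                         fat_thickness_mm = 8,
                         seed = 1L) {
  stopifnot(length(kidneys) >= 1)
  for (k in kidneys) {
    stopifnot(length(k$centre) == 3, length(k$semiaxes) == 3,
              all(k$semiaxes > 0))
  }
  if (kidney_intensity <= 50 || background_intensity >= 50)
    stop("phantom contrast must straddle the region threshold: kidney > 50 > background")
  if (body && body_intensity >= 50)
    stop("body interior must stay below the region threshold 50")
  stopifnot(bias_amplitude >= 0, bias_amplitude < 1,
            all(interslice_gain_range > 0), noise_sd >= 0,
            motion_max_translation_voxels >= 0, motion_max_rotation_deg >= 0,
            texture_kidney >= 0, texture_kidney < 0.5,
            texture_background >= 0, texture_background < 1,
            all(texture_wavelength_mm > 0))
  structure(list(
    kidneys = kidneys, spacing_inplane = as.numeric(spacing_inplane),
    slice_thickness = as.numeric(slice_thickness), shape = shape,
    margin_mm = margin_mm, kidney_intensity = kidney_intensity,
    background_intensity = background_intensity,
    cyst_intensity = cyst_intensity, n_cysts = as.integer(n_cysts),
    cyst_radius_range = as.numeric(cyst_radius_range),
    bias_amplitude = bias_amplitude,
    interslice_gain_range = as.numeric(interslice_gain_range),
    motion_max_translation_voxels = motion_max_translation_voxels,
    motion_max_rotation_deg = motion_max_rotation_deg,
    noise_sd = noise_sd,
    texture_kidney = texture_kidney,
    texture_background = texture_background,
    texture_wavelength_mm = as.numeric(texture_wavelength_mm),
    liver_abut = isTRUE(liver_abut),
    body = isTRUE(body), body_intensity = body_intensity,
    fat_intensity = fat_intensity, void_intensity = void_intensity,
    fat_thickness_mm = fat_thickness_mm,
    seed = as.integer(seed)), class = "phantom_spec")
}

# rotate in the coronal (sagittal-axial) plane about the kidney centre
local_coords <- function(x_mm, z_mm, centre, angle_deg) {
  th <- angle_deg * pi / 180
  dx <- outer(x_mm - centre[1], rep(1, length(z_mm)))
  dz <- outer(rep(1, length(x_mm)), z_mm - centre[3])
  list(u = cos(th) * dx + sin(th) * dz,
       w = -sin(th) * dx + cos(th) * dz)
}

#' Render a phantom with exact ground truth
#'
#' The clean volume is rendered first; degradations are applied in the fixed
#' order gain, bias, motion, noise. Ground-truth masks are of the clean
#' geometry and every injected degradation is returned so the corresponding
#' correction stage can be scored against it.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `vol` (degraded [image_volume()]), `clean`
#'   (undegraded volume), `masks` (list of [kidney_mask()] per kidney),
#'   `analytic_ml` (exact 4/3 pi abc volumes, ml), `gains` (per-slice gain
#'   multipliers), `bias_fields` (per-slice injected fields or `NULL`),
#'   `motion` (data frame of per-slice rigid transforms), `cysts` (placed
#'   cyst table) and `spec`.
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  sp <- c(spec$spacing_inplane[1], spec$slice_thickness, spec$spacing_inplane[2])
  if (is.null(spec$shape)) {
    lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
    for (k in spec$kidneys) {
      ext <- max(k$semiaxes[c(1, 3)])  # tilt-safe in-plane half-extent
      half <- c(ext, k$semiaxes[2], ext)
      lo <- pmin(lo, k$centre - half); hi <- pmax(hi, k$centre + half)
    }
    lo <- lo - spec$margin_mm; hi <- hi + spec$margin_mm
    shape <- pmax(ceiling((hi - lo) / sp) + 1L, 8L)
    origin <- lo
  } else {
    shape <- spec$shape
    origin <- c(0, 0, 0)
  }
  x_mm <- origin[1] + (seq_len(shape[1]) - 1) * sp[1]
  y_mm <- origin[2] + (seq_len(shape[2]) - 1) * sp[2]
  z_mm <- origin[3] + (seq_len(shape[3]) - 1) * sp[3]

  img <- array(spec$background_intensity, dim = shape)
  if (spec$body) {
    # abdominal cross-section, identical on every coronal slice: elliptical
    # body with a subcutaneous fat ring, air outside
    cx <- mean(range(x_mm)); cz <- mean(range(z_mm))
    bx <- diff(range(x_mm)) / 2 - 2; bz <- diff(range(z_mm)) / 2 - 2
    dx <- outer(x_mm - cx, rep(1, shape[3]))
    dz <- outer(rep(1, shape[1]), z_mm - cz)
    r_out <- (dx / bx)^2 + (dz / bz)^2
    r_in <- (dx / (bx - spec$fat_thickness_mm))^2 +
            (dz / (bz - spec$fat_thickness_mm))^2
    body_sl <- matrix(spec$void_intensity, shape[1], shape[3])
    body_sl[r_out <= 1] <- spec$fat_intensity
    body_sl[r_in <= 1] <- spec$body_intensity
    for (j in seq_len(shape[2])) img[, j, ] <- body_sl
  }
  masks <- vector("list", length(spec$kidneys))
  analytic_ml <- numeric(length(spec$kidneys))
  cyst_rows <- list()

  if (spec$liver_abut) {
    right_c <- spec$kidneys[[1]]$centre
    liver_half <- c(max(spec$kidneys[[1]]$semiaxes) * 0.9,
                    spec$kidneys[[1]]$semiaxes[2],
                    max(spec$kidneys[[1]]$semiaxes) * 0.8)
    liver_centre <- right_c + c(-(spec$kidneys[[1]]$semiaxes[1] + liver_half[1] + 4), 0,
                                liver_half[3] * 0.5)
    lc <- local_coords(x_mm, z_mm, liver_centre, 0)
    m2 <- (lc$u / liver_half[1])^2 + (lc$w / liver_half[3])^2
    for (j in seq_along(y_mm)) {
      vy <- ((y_mm[j] - liver_centre[2]) / liver_half[2])^2
      if (vy < 1) {
        sl <- img[, j, ]
        sl[m2 <= 1 - vy] <- spec$kidney_intensity * 0.92
        img[, j, ] <- sl
      }
    }
  }

  for (ki in seq_along(spec$kidneys)) {
    kd <- spec$kidneys[[ki]]
    ang <- if (is.null(kd$angle_deg)) 0 else kd$angle_deg
    lc <- local_coords(x_mm, z_mm, kd$centre, ang)
    m2 <- (lc$u / kd$semiaxes[1])^2 + (lc$w / kd$semiaxes[3])^2
    mk <- array(0L, dim = shape)
    for (j in seq_along(y_mm)) {
      vy <- ((y_mm[j] - kd$centre[2]) / kd$semiaxes[2])^2
      if (vy < 1) {
        inside <- m2 <= 1 - vy
        sl <- img[, j, ]
        sl[inside] <- spec$kidney_intensity
        img[, j, ] <- sl
        mk[, j, ][inside] <- 1L
      }
    }
    analytic_ml[ki] <- 4 / 3 * pi * prod(kd$semiaxes) / 1000

    # cysts: spheres fully inside the ellipsoid (in the kidney's local frame)
    placed <- 0L; tries <- 0L
    r_hi <- min(spec$cyst_radius_range[2], 0.45 * min(kd$semiaxes))
    if (spec$n_cysts > 0 && r_hi < spec$cyst_radius_range[1])
      stop(sprintf("cannot place cysts of radius >= %g mm inside kidney %d",
                   spec$cyst_radius_range[1], ki))
    while (placed < spec$n_cysts && tries < spec$n_cysts * 200L) {
      tries <- tries + 1L
      r <- stats::runif(1, spec$cyst_radius_range[1], r_hi)
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      # shrink the admissible centre region so the sphere stays inside
      shrink <- 1 - r / kd$semiaxes
      if (any(shrink <= 0)) next
      cl <- u * kd$semiaxes * shrink * 0.98
      if (sum((cl / (kd$semiaxes - r))^2) > 1) next
      th <- ang * pi / 180
      cx <- kd$centre[1] + cos(th) * cl[1] - sin(th) * cl[3]
      cz <- kd$centre[3] + sin(th) * cl[1] + cos(th) * cl[3]
      cy <- kd$centre[2] + cl[2]
      dx2 <- outer((x_mm - cx)^2, rep(1, length(z_mm)))
      dz2 <- outer(rep(1, length(x_mm)), (z_mm - cz)^2)
      for (j in seq_along(y_mm)) {
        dy2 <- (y_mm[j] - cy)^2
        if (dy2 < r^2) {
          inside <- dx2 + dz2 <= r^2 - dy2
          if (any(inside)) {
            sl <- img[, j, ]
            sl[inside] <- spec$cyst_intensity
            img[, j, ] <- sl
          }
        }
      }
      placed <- placed + 1L
      cyst_rows[[length(cyst_rows) + 1L]] <-
        data.frame(kidney = ki, x_mm = cx, y_mm = cy, z_mm = cz, r_mm = r)
    }
    if (placed < spec$n_cysts)
      stop(sprintf("could not place %d cysts inside kidney %d (placed %d)",
                   spec$n_cysts, ki, placed))
    side <- if (is.null(kd$side)) c("right", "left")[(ki - 1L) %% 2L + 1L] else kd$side
    masks[[ki]] <- kidney_mask(mk, side = side,
                               grid_link = sprintf("phantom_seed%d", spec$seed),
                               spacing_inplane = spec$spacing_inplane,
                               slice_thickness = spec$slice_thickness)
  }

  # smooth 3D anatomical texture: superposed random cosine waves with
  # mm-scale wavelengths, coherent across slices (it is anatomy, so it moves
  # with any injected motion). Mild inside parenchyma, strong in the
  # background (organ clutter), absent in fluid-filled cysts.
  if (spec$texture_kidney > 0 || spec$texture_background > 0) {
    nw <- 12L
    dirs <- matrix(stats::rnorm(3 * nw), nw, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    lam <- stats::runif(nw, spec$texture_wavelength_mm[1],
                        spec$texture_wavelength_mm[2])
    kvec <- dirs * (2 * pi / lam)
    phs <- stats::runif(nw, 0, 2 * pi)
    Xmm <- outer(x_mm, rep(1, shape[3]))
    Zmm <- outer(rep(1, shape[1]), z_mm)
    any_kidney <- array(0L, dim = shape)
    for (mk in masks) any_kidney <- any_kidney | mk$voxels
    for (j in seq_len(shape[2])) {
      tex <- matrix(0, shape[1], shape[3])
      for (i in seq_len(nw))
        tex <- tex + cos(kvec[i, 1] * Xmm + kvec[i, 3] * Zmm +
                         kvec[i, 2] * y_mm[j] + phs[i])
      tex <- tex * sqrt(2 / nw)  # unit variance
      sl <- img[, j, ]
      amp <- matrix(spec$texture_background, shape[1], shape[3])
      amp[sl > 50] <- spec$texture_kidney                 # any tissue
      amp[sl == spec$cyst_intensity] <- 0                 # fluid: homogeneous
      sl <- pmax(sl * (1 + amp * tex), 0.5)
      img[, j, ] <- sl
    }
  }

  clean <- image_volume(img, spec$spacing_inplane, spec$slice_thickness,
                        source_id = sprintf("phantom_seed%d", spec$seed))

  # --- degradations, fixed order: gain -> bias -> motion -> noise ---
  nk <- shape[2]
  gains <- stats::runif(nk, spec$interslice_gain_range[1],
                        spec$interslice_gain_range[2])
  deg <- img
  if (any(gains != 1))
    for (j in seq_len(nk)) deg[, j, ] <- deg[, j, ] * gains[j]

  bias_fields <- NULL
  if (spec$bias_amplitude > 0) {
    bias_fields <- vector("list", nk)
    xn <- seq(-1, 1, length.out = shape[1])
    zn <- seq(-1, 1, length.out = shape[3])
    X <- outer(xn, rep(1, shape[3])); Z <- outer(rep(1, shape[1]), zn)
    for (j in seq_len(nk)) {
      cf <- stats::runif(5, -1, 1)
      f <- cf[1] * X + cf[2] * Z + cf[3] * X^2 + cf[4] * X * Z + cf[5] * Z^2
      f <- f / max(abs(f))
      fld <- 1 + spec$bias_amplitude * f
      fld <- fld / mean(fld)
      bias_fields[[j]] <- fld
      deg[, j, ] <- deg[, j, ] * fld
    }
  }

  ref <- (nk + 1L) %/% 2L
  motion <- data.frame(slice = seq_len(nk), angle_deg = 0, tx = 0, ty = 0)
  if (spec$motion_max_translation_voxels > 0 || spec$motion_max_rotation_deg > 0) {
    for (j in seq_len(nk)) {
      if (j == ref) next
      motion$angle_deg[j] <- stats::runif(1, -spec$motion_max_rotation_deg,
                                          spec$motion_max_rotation_deg)
      motion$tx[j] <- stats::runif(1, -spec$motion_max_translation_voxels,
                                   spec$motion_max_translation_voxels)
      motion$ty[j] <- stats::runif(1, -spec$motion_max_translation_voxels,
                                   spec$motion_max_translation_voxels)
      deg[, j, ] <- apply_rigid2d(deg[, j, ], motion$angle_deg[j],
                                  motion$tx[j], motion$ty[j],
                                  fill = if (spec$body) spec$void_intensity
                                         else spec$background_intensity)
    }
  }

  if (spec$noise_sd > 0)
    deg <- pmax(deg + stats::rnorm(length(deg), 0, spec$noise_sd), 0)

  vol <- image_volume(deg, spec$spacing_inplane, spec$slice_thickness,
                      source_id = sprintf("phantom_seed%d", spec$seed))
  list(vol = vol, clean = clean, masks = masks, analytic_ml = analytic_ml,
       gains = gains, bias_fields = bias_fields, motion = motion,
       reference_slice = ref, origin_mm = origin,
       cysts = if (length(cyst_rows)) do.call(rbind, cyst_rows) else NULL,
       spec = spec)
}

# realistic ADPKD kidney proportions: length : width : depth ~ 2.1 : 1.25 : 1
kidney_from_volume <- function(kv_ml, centre, side, angle_deg = 0,
                               ratios = c(2.1, 1.25, 1)) {
  s <- (kv_ml * 1000 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
  ax <- ratios * s
  # semiaxes in canonical order: left-right = width, ant-post = depth,
  # sup-inf = length
  list(centre = centre, semiaxes = c(ax[2], ax[3], ax[1]),
       angle_deg = angle_deg, side = side)
}

#' Build a two-kidney phantom spec with a requested total kidney volume
#'
#' Kidney shape uses fixed anatomical proportions
#' (length : width : depth of roughly 2.1 : 1.25 : 1) scaled to hit the
#' requested TKV exactly (analytically), with a left/right volume split and
#' small tilts in the coronal plane.
#'
#' @param tkv_ml requested analytic total kidney volume.
#' @param right_fraction fraction of TKV in the right kidney.
#' @param tilt_deg length-2 tilt angles (right, left) about the
#'   anterior-posterior axis.
#' @param ... passed to [phantom_spec()].
#' @return a [phantom_spec()] with two kidneys.
#' @export
phantom_two_kidney_spec <- function(tkv_ml, right_fraction = 0.5,
                                    tilt_deg = c(8, -8), ...) {
  stopifnot(tkv_ml > 0, right_fraction > 0, right_fraction < 1)
  kv_r <- tkv_ml * right_fraction
  kv_l <- tkv_ml - kv_r
  sep <- 1.35 * ((max(kv_r, kv_l) * 1000 / (4 / 3 * pi * 2.625))^(1 / 3)) * 1.25
  right <- kidney_from_volume(kv_r, centre = c(-sep, 0, 0), side = "right",
                              angle_deg = tilt_deg[1])
  left <- kidney_from_volume(kv_l, centre = c(sep, 0, 0), side = "left",
                             angle_deg = tilt_deg[2])
  phantom_spec(kidneys = list(right, left), ...)
}

#' Deterministic phantom cohort spanning a TKV range
#'
#' Case TKVs are evenly spaced on the log scale between the range endpoints
#' (a single case sits at the log-midpoint); per-case degradation seeds,
#' left/right splits and tilts derive deterministically from `seed`. The
#' cohort emulates a cross-sectional ADPKD population spanning mild to severe
#' enlargement.
#'
#' @param n number of cases (>= 1).
#' @param size_range_ml length-2 analytic TKV range in ml.
#' @param seed integer master seed.
#' @param ... overrides passed to [phantom_two_kidney_spec()] for every case
#'   (e.g. degradations, resolution).
#' @return list of [phantom_spec()] objects of length `n`.
#' @export
phantom_cohort <- function(n, size_range_ml = c(258, 3680), seed = 1L, ...) {
  stopifnot(n >= 1)
  if (length(size_range_ml) != 2 || any(size_range_ml <= 0) ||
      size_range_ml[2] < size_range_ml[1] ||
      (n > 1 && size_range_ml[2] == size_range_ml[1]))
    stop("size_range_ml must be a positive, non-empty range")
  tkvs <- if (n == 1) sqrt(prod(size_range_ml))
          else exp(seq(log(size_range_ml[1]), log(size_range_ml[2]),
                       length.out = n))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fr <- stats::runif(n, 0.44, 0.56)
  tr <- stats::runif(n, -14, 14)
  tl <- stats::runif(n, -14, 14)
  lapply(seq_len(n), function(i)
    phantom_two_kidney_spec(tkv_ml = tkvs[i], right_fraction = fr[i],
                            tilt_deg = c(tr[i], tl[i]),
                            seed = seed * 1000L + i, ...))
}
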