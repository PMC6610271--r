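# Pre-processing of the selected coronal slices: rigid in-plane motion
# correction (slice-to-neighbour registration chained from a central
# reference), intra-slice bias-field correction by entropy minimisation over
# a low-order multiplicative polynomial field, inter-slice gain normalisation
# against bright tissue, and ROI cropping. Order is fixed as
# motion -> bias -> inter-slice.

# --- rigid 2D resampling ----------------------------------------------------

# bilinear sample of `img` at (xi, yi) (1-based, matrix row/col coordinates)
bilinear_sample <- function(img, xi, yi, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 1 & x0 <= nr - 1 & y0 >= 1 & y0 <= nc - 1
  x0c <- pmin(pmax(x0, 1), nr - 1); y0c <- pmin(pmax(y0, 1), nc - 1)
  i00 <- cbind(as.vector(x0c), as.vector(y0c))
  v <- (img[i00] * (1 - fx) + img[cbind(i00[, 1] + 1L, i00[, 2])] * fx) * (1 - fy) +
       (img[cbind(i00[, 1], i00[, 2] + 1L)] * (1 - fx) +
        img[cbind(i00[, 1] + 1L, i00[, 2] + 1L)] * fx) * fy
  v[!ok] <- fill
  matrix(v, nr, nc)
}

# apply a rigid transform (rotation about the slice centre, then translation,
# in voxel units) to a slice: out(p) = in(Rinv (p - c - t) + c)
apply_rigid2d <- function(slice, angle_deg, tx, ty, fill = 0) {
  if (angle_deg == 0 && tx == 0 && ty == 0) return(slice)
  nr <- nrow(slice); nc <- ncol(slice)
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  px <- outer(seq_len(nr), rep(1, nc)) - cx - tx
  py <- outer(rep(1, nr), seq_len(nc)) - cy - ty
  xi <- cos(th) * px + sin(th) * py + cx
  yi <- -sin(th) * px + cos(th) * py + cy
  bilinear_sample(slice, xi, yi, fill = fill)
}

invert_rigid2d <- function(angle_deg, tx, ty) {
  th <- angle_deg * pi / 180
  c(angle_deg = -angle_deg,
    tx = -(cos(th) * tx + sin(th) * ty),
    ty = -(-sin(th) * tx + cos(th) * ty))
}

downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  m <- img[seq_len(nr), seq_len(nc)]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
   m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

# smoothed gradient magnitude; rotation-invariant, so it commutes with the
# rigid warp
grad_mag <- function(m, sigma = 1.5) {
  sm <- as.matrix(EBImage::gblur(m, sigma = sigma))
  sqrt(diff_x(sm)^2 + diff_y(sm)^2)
}

# mean-squared-error rigid registration of `moving` onto `fixed`, computed
# on smoothed gradient-magnitude images (edges constrain the alignment even
# where neighbouring slices differ in cross-section, which would leave a
# flat plateau in a raw-intensity objective), multi-resolution (coarse
# translation sweep at half resolution, then Nelder-Mead refinement at full
# resolution) over rotation +/- max_rot deg and translation +/- max_trans
# voxels
register_rigid2d <- function(moving, fixed, max_rot = 5, max_trans = 5) {
  if (stats::sd(moving) < 1e-9 || stats::sd(fixed) < 1e-9) {
    warning("blank slice in registration; returning identity transform")
    return(c(angle_deg = 0, tx = 0, ty = 0))
  }
  mg <- grad_mag(moving); fg <- grad_mag(fixed)
  wI <- 1 / (stats::var(as.vector(fixed)) + 1e-9)
  wG <- 1 / (stats::var(as.vector(fg)) + 1e-9)
  obj <- function(p, mov, fix, movg, fixg, wi, wg) {
    pen <- sum(pmax(abs(p) - c(max_rot, max_trans, max_trans), 0)^2)
    w1 <- apply_rigid2d(mov, p[1], p[2], p[3], fill = NA)
    w2 <- apply_rigid2d(movg, p[1], p[2], p[3], fill = NA)
    wi * mean((w1 - fix)^2, na.rm = TRUE) +
      wg * mean((w2 - fixg)^2, na.rm = TRUE) + pen
  }
  mov2 <- downsample2(moving); fix2 <- downsample2(fixed)
  mg2 <- downsample2(mg); fg2 <- downsample2(fg)
  wI2 <- 1 / (stats::var(as.vector(fix2)) + 1e-9)
  wG2 <- 1 / (stats::var(as.vector(fg2)) + 1e-9)
  grid <- expand.grid(tx = seq(-max_trans / 2, max_trans / 2, by = 1),
                      ty = seq(-max_trans / 2, max_trans / 2, by = 1))
  vals <- vapply(seq_len(nrow(grid)),
                 function(i) obj(c(0, grid$tx[i], grid$ty[i]), mov2, fix2,
                                 mg2, fg2, wI2, wG2),
                 numeric(1))
  p0 <- c(0, as.numeric(grid[which.min(vals), ]))
  fit2 <- stats::optim(p0, obj, mov = mov2, fix = fix2, movg = mg2, fixg = fg2,
                       wi = wI2, wg = wG2, method = "Nelder-Mead",
                       control = list(maxit = 150, reltol = 1e-7))
  p1 <- fit2$par * c(1, 2, 2)  # translations back to full-resolution voxels
  fit <- stats::optim(p1, obj, mov = moving, fix = fixed, movg = mg, fixg = fg,
                      wi = wI, wg = wG, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  stats::setNames(fit$par, c("angle_deg", "tx", "ty"))
}

# --- operations -------------------------------------------------------------

#' Sagittal landmark marking the kidney's anterior-posterior extent
#'
#' Two points picked on (approximately) the mid-sagittal slice through the
#' kidney; their anterior-posterior span determines which coronal slices
#' contain the kidney. On a sagittal slice, rows index the coronal
#' (anterior-posterior) direction and columns the axial direction, so a
#' point's first coordinate is directly a coronal slice index.
#'
#' @param slice_index 1-based sagittal slice index.
#' @param edge_points 2 x 2 matrix, one point per row:
#'   (coronal index, axial index).
#' @return An object of class `sagittal_landmark`.
#' @export
sagittal_landmark <- function(slice_index, edge_points) {
  edge_points <- as.matrix(edge_points)
  if (!all(dim(edge_points) == c(2, 2)))
    stop("`edge_points` must be a 2 x 2 matrix (two points)")
  if (all(edge_points[1, ] == edge_points[2, ]))
    stop("degenerate landmark: the two points coincide")
  structure(list(slice_index = as.integer(slice_index),
                 edge_points = edge_points), class = "sagittal_landmark")
}

#' Select the coronal slices containing the kidney
#'
#' The anterior-posterior span of the two landmark points, dilated by
#' `margin` slices and clipped to the volume, defines the working slice range.
#'
#' @param vol an [image_volume()].
#' @param landmark a [sagittal_landmark()].
#' @param margin extra slices added on both sides.
#' @return integer vector `c(first, last)` of 1-based coronal slice indices.
#' @export
select_coronal_slices <- function(vol, landmark, margin = 2L) {
  stopifnot(is_image_volume(vol), inherits(landmark, "sagittal_landmark"))
  d <- dim(vol$voxels)
  ns <- d[axis_dim(vol, "sagittal")]
  if (landmark$slice_index < 1 || landmark$slice_index > ns)
    stop("landmark sagittal slice index outside the volume")
  nk <- n_coronal(vol)
  ap <- landmark$edge_points[, 1]
  if (any(ap < 1) || any(ap > nk))
    stop("landmark points outside the sagittal slice bounds")
  first <- max(1L, floor(min(ap)) - margin)
  last <- min(nk, ceiling(max(ap)) + margin)
  c(first = as.integer(first), last = as.integer(last))
}

check_range <- function(vol, range) {
  if (length(range) != 2 || range[1] < 1 || range[2] > n_coronal(vol) ||
      range[1] > range[2])
    stop("invalid coronal slice range")
  as.integer(range)
}

#' Correct inter-slice motion by chained rigid registration
#'
#' Each slice in the range is registered (rotation + in-plane translation,
#' mean-squared-error objective) to its already-corrected neighbour, chaining
#' outward from the central reference slice, and resampled by the recovered
#' transform. The reference slice's transform is the identity.
#'
#' @param vol an [image_volume()].
#' @param range coronal slice range `c(first, last)`.
#' @param max_rot,max_trans search bounds: degrees and voxels.
#' @param reference reference slice index (identity transform); defaults to
#'   the centre of the range.
#' @return list with `vol` (motion-corrected volume) and `motion` (data frame
#'   of per-slice recovered transforms, class `motion_model`).
#' @export
correct_motion <- function(vol, range = c(1L, n_coronal(vol)),
                           max_rot = 5, max_trans = 5, reference = NULL) {
  range <- check_range(vol, range)
  idx <- range[1]:range[2]
  ref <- if (is.null(reference)) idx[(length(idx) + 1L) %/% 2L]
         else as.integer(reference)
  if (!ref %in% idx) stop("reference slice outside the range")
  motion <- data.frame(slice = idx, angle_deg = 0, tx = 0, ty = 0)
  # slices with almost no structure (noise-only background) cannot anchor a
  # registration; they keep the identity transform
  slice_sd <- vapply(idx, function(k) stats::sd(coronal_slice(vol, k)), numeric(1))
  sd_floor <- 0.1 * max(slice_sd)
  out <- vol
  for (dir in c(-1L, 1L)) {
    prev <- coronal_slice(out, ref)
    k <- ref + dir
    while (k >= range[1] && k <= range[2]) {
      if (slice_sd[match(k, idx)] < sd_floor) {
        k <- k + dir
        next
      }
      p <- register_rigid2d(coronal_slice(vol, k), prev,
                            max_rot = max_rot, max_trans = max_trans)
      corrected <- apply_rigid2d(coronal_slice(vol, k), p[1], p[2], p[3],
                                 fill = stats::median(coronal_slice(vol, k)))
      out <- set_coronal_slice(out, k, corrected)
      motion[motion$slice == k, c("angle_deg", "tx", "ty")] <- as.list(p)
      prev <- corrected
      k <- k + dir
    }
  }
  class(motion) <- c("motion_model", "data.frame")
  attr(motion, "reference_slice") <- ref
  list(vol = out, motion = motion)
}

# entropy of a linearly-binned (hence continuous in the data) histogram
hist_entropy <- function(values, breaks) {
  nb <- length(breaks) - 1L
  w <- (breaks[2] - breaks[1])
  pos <- (values - breaks[1]) / w + 0.5
  pos <- pmin(pmax(pos, 0.5000001), nb + 0.4999999)
  lo <- floor(pos - 0.5) + 1L
  frac <- pos - 0.5 - (lo - 1L)
  counts <- numeric(nb + 1L)
  t1 <- tapply((1 - frac), lo, sum)
  t2 <- tapply(frac, lo + 1L, sum)
  counts[as.integer(names(t1))] <- counts[as.integer(names(t1))] + t1
  counts[as.integer(names(t2))] <- counts[as.integer(names(t2))] + t2
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Correct the intra-slice bias field by histogram-entropy minimisation
#'
#' A smooth, strictly positive multiplicative field
#' `exp(polynomial(x, z))` of low order is fitted by minimising the entropy
#' of the corrected slice's intensity histogram (linear binning over the
#' slice's occupied range); the corrected slice is `slice / field` and the
#' field is normalised to unit mean so the slice's mean intensity is
#' preserved. A near-constant slice is returned unchanged.
#'
#' @param slice numeric matrix (one coronal slice).
#' @param order polynomial order of the log-field (default 2).
#' @param bins histogram bin count.
#' @param lambda ridge penalty on the polynomial coefficients, keeping the
#'   field at 1 when the data carry no bias signal.
#' @param maxit optimiser iteration cap.
#' @return list with `corrected` (matrix), `field` (matrix, unit mean) and
#'   `entropy` (before/after).
#' @export
correct_bias_field <- function(slice, order = 2L, bins = 64L,
                               lambda = 1e-3, maxit = 400L) {
  rng <- range(slice)
  if (diff(rng) < 1e-9) {
    return(list(corrected = slice, field = matrix(1, nrow(slice), ncol(slice)),
                entropy = c(before = 0, after = 0)))
  }
  nr <- nrow(slice); nc <- ncol(slice)
  xn <- seq(-1, 1, length.out = nr); zn <- seq(-1, 1, length.out = nc)
  X <- outer(xn, rep(1, nc)); Z <- outer(rep(1, nr), zn)
  terms <- list()
  for (i in 0:order) for (j in 0:order)
    if (i + j >= 1 && i + j <= order) terms[[length(terms) + 1L]] <- X^i * Z^j
  B <- vapply(terms, as.vector, numeric(nr * nc))

  pad <- diff(rng) * 0.35  # room for corrected values to move
  breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = bins + 1L)
  v <- as.vector(slice)
  ent0 <- hist_entropy(v, breaks)
  obj <- function(theta) {
    lf <- B %*% theta
    f <- exp(lf - log(mean(exp(lf))))
    hist_entropy(v / f, breaks) + lambda * sum(theta^2)
  }
  fit <- stats::optim(rep(0, ncol(B)), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  lf <- B %*% fit$par
  field <- matrix(exp(lf - log(mean(exp(lf)))), nr, nc)
  corrected <- slice / field
  list(corrected = corrected, field = field,
       entropy = c(before = ent0, after = hist_entropy(as.vector(corrected), breaks)))
}

#' Normalise inter-slice intensity variation
#'
#' Per slice, bright tissue is voxels above `threshold_frac` times the slice's
#' robust maximum (99th percentile, resisting hot pixels); a per-slice scalar
#' multiplier is fitted by least squares so each slice's mean bright-tissue
#' intensity matches the median of those means across slices. Slices with no
#' voxel above threshold keep multiplier 1 with a warning.
#'
#' @param vol an [image_volume()].
#' @param range coronal slice range.
#' @param threshold_frac fraction of the robust slice maximum defining bright
#'   tissue (default 0.5, "half-slice maximum").
#' @return list with `vol` (normalised volume) and `gains` (data frame of
#'   per-slice multipliers, class `gain_profile`).
#' @export
normalize_interslice <- function(vol, range = c(1L, n_coronal(vol)),
                                 threshold_frac = 0.5) {
  range <- check_range(vol, range)
  idx <- range[1]:range[2]
  # the per-slice threshold must stay relative to the slice's own robust
  # maximum (that is what makes it invariant to the very gain drift being
  # corrected); the volume-wide reference is only a veto for slices that
  # contain no tissue at all, whose background would otherwise be classified
  # as "bright" and boosted to the target
  floor_global <- 0.25 *
    stats::quantile(vol$voxels[, idx, , drop = FALSE], 0.99, names = FALSE)
  means <- rep(NA_real_, length(idx))
  for (i in seq_along(idx)) {
    sl <- coronal_slice(vol, idx[i])
    q99 <- stats::quantile(sl, 0.99, names = FALSE)
    if (q99 < floor_global) next
    bright <- sl > threshold_frac * q99
    if (any(bright)) means[i] <- mean(sl[bright])
  }
  if (all(is.na(means))) stop("no slice contains bright tissue above threshold")
  target <- stats::median(means, na.rm = TRUE)
  mult <- target / means
  if (anyNA(mult)) {
    warning("slice(s) with no bright tissue kept at multiplier 1")
    mult[is.na(mult)] <- 1
  }
  out <- vol
  for (i in seq_along(idx))
    out <- set_coronal_slice(out, idx[i], coronal_slice(vol, idx[i]) * mult[i])
  gains <- data.frame(slice = idx, multiplier = mult,
                      bright_mean = means, target = target)
  class(gains) <- c("gain_profile", "data.frame")
  list(vol = out, gains = gains)
}

#' Crop a rectangular region of interest over a slice range
#'
#' The crop offset and the full grid shape are recorded as attributes so
#' masks computed on the cropped grid can be mapped back exactly with
#' [uncrop_mask()]. Spacing is unchanged.
#'
#' @param vol an [image_volume()].
#' @param rect integer vector `c(row_min, row_max, col_min, col_max)` in
#'   coronal-slice coordinates (rows sagittal, columns axial), 1-based
#'   inclusive.
#' @param range coronal slice range `c(first, last)`.
#' @return a cropped [image_volume()] with attributes `crop_offset` and
#'   `crop_fullshape`.
#' @export
crop_roi <- function(vol, rect, range = c(1L, n_coronal(vol))) {
  range <- check_range(vol, range)
  rect <- as.integer(rect)
  d <- dim(vol$voxels)
  if (length(rect) != 4 || rect[1] > rect[2] || rect[3] > rect[4])
    stop("empty or malformed rectangle")
  if (rect[1] < 1 || rect[2] > d[1] || rect[3] < 1 || rect[4] > d[3])
    stop("rectangle outside slice bounds")
  sub <- vol$voxels[rect[1]:rect[2], range[1]:range[2], rect[3]:rect[4], drop = FALSE]
  out <- image_volume(sub, vol$spacing_inplane, vol$slice_thickness,
                      source_id = vol$source_id)
  attr(out, "crop_offset") <- c(rect[1] - 1L, range[1] - 1L, rect[3] - 1L)
  attr(out, "crop_fullshape") <- d
  out
}

#' Map a mask on a cropped grid back to the full grid
#'
#' @param mask a [kidney_mask()] on a grid produced by [crop_roi()].
#' @param cropped_vol the cropped volume carrying the crop attributes.
#' @return a [kidney_mask()] on the full grid; voxel positions are preserved
#'   exactly.
#' @export
uncrop_mask <- function(mask, cropped_vol) {
  off <- attr(cropped_vol, "crop_offset")
  full <- attr(cropped_vol, "crop_fullshape")
  if (is.null(off) || is.null(full)) stop("volume carries no crop information")
  d <- dim(mask$voxels)
  big <- array(0L, dim = full)
  big[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <-
    mask$voxels
  kidney_mask(big, side = mask$side, grid_link = mask$grid_link,
              spacing_inplane = mask$spacing_inplane,
              slice_thickness = mask$slice_thickness)
}
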