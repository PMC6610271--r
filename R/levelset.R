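# Hybrid level-set segmentation: a region force driving the contour outward
# where intensity exceeds the threshold mu and inward below it, regularised
# by an edge-weighted geodesic (curvature + edge-attraction) flow. The
# energy, with phi negative inside and H a smoothed step,
#
#   E(phi) = -alpha * int (I - mu) (1 - H(phi)) dOmega
#            + beta * int g |grad H(phi)| dOmega,
#
# is descended explicitly:
#
#   phi_t = delta_eps(phi) [ beta * div(g grad(phi)/|grad(phi)|)
#                            - alpha (I - mu) ].
#
# g = 1/(1 + c |grad I|^2) is the edge map (small on boundaries, halting the
# contour there); the printed form with a minus sign in the denominator is
# singular at strong edges and is treated as a typographical slip.

#' Parameters of the hybrid level-set energy
#'
#' Defaults are the validated operating point on images rescaled so the 99th
#' intensity percentile maps to 255: region weight `alpha = 0.01`, edge
#' weight `beta = 100`, region threshold `mu = 50`, 100 evolution steps.
#' `cc` sets the slope of the edge map, `heaviside_eps` the smoothing width
#' (voxels) of the Heaviside step, `dt` the base explicit time step (the
#' actual step is preconditioned pointwise so the edge-diffusion term always
#' stays inside its stability bound), and `redist_every` the re-distancing
#' cadence.
#'
#' @param alpha region-term weight.
#' @param beta edge-term weight.
#' @param mu region intensity threshold (the energy's u).
#' @param cc edge-map slope constant.
#' @param iterations evolution steps.
#' @param heaviside_eps Heaviside smoothing width, voxels.
#' @param dt base time step of the preconditioned explicit scheme.
#' @param smooth_sigma Gaussian sigma (voxels) applied to the image before
#'   the edge-map gradient.
#' @param redist_every re-initialise phi toward a signed distance every this
#'   many iterations.
#' @return An object of class `levelset_params`.
#' @export
levelset_params <- function(alpha = 0.01, beta = 100, mu = 50, cc = 1,
                            iterations = 100L, heaviside_eps = 1.5,
                            dt = 0.5, smooth_sigma = 2,
                            redist_every = 10L) {
  stopifnot(alpha > 0, beta > 0, cc > 0, heaviside_eps > 0, dt > 0,
            iterations >= 1, smooth_sigma > 0, redist_every >= 1)
  structure(list(alpha = alpha, beta = beta, mu = mu, cc = cc,
                 iterations = as.integer(iterations),
                 heaviside_eps = heaviside_eps, dt = dt,
                 smooth_sigma = smooth_sigma,
                 redist_every = as.integer(redist_every)),
            class = "levelset_params")
}

# central differences with replicated (Neumann) borders
diff_x <- function(m) {
  nr <- nrow(m)
  (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
}
diff_y <- function(m) {
  nc <- ncol(m)
  (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
}

#' Edge (boundary) map of a slice
#'
#' `g = 1 / (1 + c |grad I|^2)` computed on a lightly Gaussian-smoothed
#' image; `g` is in (0, 1], equals 1 where the gradient vanishes and drops
#' toward 0 on boundaries, which is where the geodesic term halts the
#' contour.
#'
#' @param slice numeric matrix.
#' @param cc slope constant.
#' @param smooth_sigma Gaussian smoothing sigma in voxels.
#' @return matrix `g`, same shape as `slice`.
#' @export
edge_map <- function(slice, cc = 1, smooth_sigma = 1.5) {
  stopifnot(all(is.finite(slice)))
  sm <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(slice, sigma = smooth_sigma))
        else slice
  1 / (1 + cc * (diff_x(sm)^2 + diff_y(sm)^2))
}

# signed distance (negative inside) from a binary region
sdf_from_region <- function(region) {
  if (!any(region)) return(matrix(1e6, nrow(region), ncol(region)))
  if (all(region)) return(matrix(-1e6, nrow(region), ncol(region)))
  d_in <- as.matrix(EBImage::distmap(matrix(as.numeric(region), nrow(region))))
  d_out <- as.matrix(EBImage::distmap(matrix(as.numeric(!region), nrow(region))))
  d_out - d_in
}

#' Seed contour for level-set initialisation
#'
#' An ordered, simple (non-self-intersecting) closed polygon drawn near the
#' kidney boundary on the mid-coronal slice.
#'
#' @param slice_index 1-based coronal slice index.
#' @param points n x 2 matrix of (row, col) vertices, n >= 3, in
#'   coronal-slice voxel coordinates.
#' @return An object of class `seed_contour`.
#' @export
seed_contour <- function(slice_index, points) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 2)
    stop("seed polygon needs at least 3 (row, col) vertices")
  a <- polygon_area(points)
  if (abs(a) < 1e-9) stop("degenerate seed polygon (zero area)")
  if (!polygon_is_simple(points)) stop("seed polygon is self-intersecting")
  structure(list(slice_index = as.integer(slice_index), points = points),
            class = "seed_contour")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  idx <- rbind(cbind(1:n, c(2:n, 1)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # skip adjacent edges (they share a vertex)
    if (abs(i - j) <= 1 || (i == 1 && j == n)) next
    if (segments_intersect(p[idx[i, 1], ], p[idx[i, 2], ],
                           p[idx[j, 1], ], p[idx[j, 2], ])) return(FALSE)
  }
  TRUE
}

# even-odd rasterisation: which voxel centres fall inside the polygon
rasterize_polygon <- function(points, shape) {
  nr <- shape[1]; nc <- shape[2]
  gx <- as.vector(outer(seq_len(nr), rep(1, nc)))
  gy <- as.vector(outer(rep(1, nr), seq_len(nc)))
  inside <- rep(FALSE, nr * nc)
  n <- nrow(points)
  j <- n
  for (i in seq_len(n)) {
    xi <- points[i, 1]; yi <- points[i, 2]
    xj <- points[j, 1]; yj <- points[j, 2]
    crosses <- ((yi > gy) != (yj > gy)) &
      (gx < (xj - xi) * (gy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Initialise the level-set field from a seed contour
#'
#' `phi` is the signed distance to the seed polygon, negative inside.
#'
#' @param seed a [seed_contour()].
#' @param slice_shape `c(rows, cols)` of the slice grid.
#' @return numeric matrix `phi`.
#' @export
init_phi <- function(seed, slice_shape) {
  stopifnot(inherits(seed, "seed_contour"))
  if (any(seed$points[, 1] < 1) || any(seed$points[, 1] > slice_shape[1]) ||
      any(seed$points[, 2] < 1) || any(seed$points[, 2] > slice_shape[2]))
    stop("seed polygon outside the slice")
  region <- rasterize_polygon(seed$points, slice_shape)
  if (!any(region)) stop("seed polygon rasterises to an empty region")
  sdf_from_region(region)
}

#' Evolve the level-set field on one slice
#'
#' Explicit gradient descent on the hybrid energy for `params$iterations`
#' steps: the interface moves outward where `I > mu` and inward where
#' `I < mu` (region force `alpha (I - mu)`), regularised by the edge-weighted
#' curvature flow and attracted to boundaries by the edge-map gradient
#' (the `beta` term). `phi` is pulled back toward a signed-distance profile
#' every `params$redist_every` steps. Evolution is fully deterministic.
#'
#' @param phi initial field (e.g. from [init_phi()]), negative inside.
#' @param slice image matrix, on the working intensity scale.
#' @param g edge map from [edge_map()]; computed from `slice` if `NULL`.
#' @param params a [levelset_params()].
#' @return the evolved `phi` matrix.
#' @export
evolve <- function(phi, slice, g = NULL, params = levelset_params()) {
  stopifnot(identical(dim(phi), dim(slice)))
  if (is.null(g)) g <- edge_map(slice, params$cc, params$smooth_sigma)
  gx_g <- diff_x(g); gy_g <- diff_y(g)
  eps <- params$heaviside_eps
  reg <- params$alpha * (slice - params$mu)
  # Jacobi-preconditioned explicit step: the spatially varying positive step
  # keeps the edge-diffusion (curvature) term unconditionally inside its
  # stability bound (effective diffusion coefficient <= 1/4) without slowing
  # the advection/region forces where g is small; a positive pointwise step
  # leaves the energy's stationary contours unchanged.
  step <- params$dt / (1 + 4 * params$dt * params$beta * g)
  for (it in seq_len(params$iterations)) {
    px <- diff_x(phi); py <- diff_y(phi)
    mag <- sqrt(px^2 + py^2 + 1e-8)
    nx <- px / mag; ny <- py / mag
    curv <- diff_x(nx) + diff_y(ny)
    force <- params$beta * (g * curv + gx_g * nx + gy_g * ny) - reg
    upd <- pmin(pmax(step * force, -0.5), 0.5)  # <= half a voxel per step
    delta_n <- eps^2 / (eps^2 + phi^2)  # unit-peak smoothed delta band
    phi <- phi + delta_n * upd
    if (!all(is.finite(phi)))
      stop("non-finite values during level-set evolution; reduce dt")
    if (it %% params$redist_every == 0L && it < params$iterations) {
      region <- phi < 0
      if (!any(region)) return(phi)  # region vanished; nothing left to evolve
      phi <- sdf_from_region(region)
    }
  }
  phi
}

#' Rescale a volume to the working intensity scale
#'
#' Linear rescale mapping the given percentile (default 99th) to 255, making
#' the region threshold `mu = 50` meaningful across scanners and phantoms.
#'
#' @param vol an [image_volume()].
#' @param prob percentile mapped to `target`.
#' @param target upper anchor of the working scale.
#' @return the rescaled volume.
#' @export
rescale_intensity <- function(vol, prob = 0.99, target = 255) {
  q <- stats::quantile(vol$voxels, prob, names = FALSE)
  if (q <= 0) stop("cannot rescale: reference percentile is non-positive")
  out <- vol
  out$voxels <- vol$voxels * (target / q)
  out
}

erode_region <- function(region) {
  if (!any(region)) return(region)
  m <- EBImage::erode(matrix(as.numeric(region), nrow(region)),
                      EBImage::makeBrush(3, shape = "box"))
  as.matrix(m) > 0.5
}

dilate_region <- function(region) {
  if (!any(region)) return(region)
  m <- EBImage::dilate(matrix(as.numeric(region), nrow(region)),
                       EBImage::makeBrush(3, shape = "box"))
  as.matrix(m) > 0.5
}

#' Segment one kidney through the slice stack
#'
#' The user-seeded mid-coronal slice is segmented first; the resulting region
#' then propagates slice-by-slice in both directions, each new slice
#' initialised with the signed distance of the previous slice's final region
#' eroded by one voxel (the erosion prevents leakage where the kidney
#' narrows), and evolved with the same parameters. Propagation in a direction
#' stops when a slice's region becomes empty. Input is expected to be
#' pre-processed and cropped; intensities are rescaled internally so the
#' region threshold is on its working scale.
#'
#' @param vol a (pre-processed, cropped) [image_volume()].
#' @param seed a [seed_contour()] on the mid-coronal slice.
#' @param params a [levelset_params()].
#' @param side kidney side label for the output mask.
#' @param rescale rescale intensities (99th percentile to 255) first.
#' @return a [kidney_mask()] on the grid of `vol`.
#' @export
segment_kidney <- function(vol, seed, params = levelset_params(),
                           side = c("left", "right"), rescale = TRUE) {
  stopifnot(is_image_volume(vol), inherits(seed, "seed_contour"))
  side <- match.arg(side)
  nk <- n_coronal(vol)
  if (seed$slice_index < 1 || seed$slice_index > nk)
    stop("seed slice index outside the volume")
  work <- if (rescale) rescale_intensity(vol) else vol
  shape2 <- dim(coronal_slice(work, 1))
  mask <- array(0L, dim = dim(vol$voxels))

  mid <- seed$slice_index
  phi <- init_phi(seed, shape2)
  sl <- coronal_slice(work, mid)
  phi <- evolve(phi, sl, NULL, params)
  region_mid <- phi < 0
  if (!any(region_mid)) stop("empty mid-slice segmentation result")
  mask[, mid, ] <- as.integer(region_mid)

  for (dir in c(-1L, 1L)) {
    prev <- region_mid
    k <- mid + dir
    while (k >= 1 && k <= nk) {
      sl <- coronal_slice(work, k)
      # initialise from the previous slice's region (eroded, so the contour
      # cannot leak where the kidney narrows) restricted to the region
      # model's super-threshold set (dilated one voxel, so the true boundary
      # stays inside); where the kidney cross-section collapses between
      # slices this starts the contour at the new section instead of leaving
      # it stranded on background it cannot cross in the iteration budget
      init_region <- erode_region(prev) & dilate_region(sl > params$mu)
      if (!any(init_region)) break
      phi <- sdf_from_region(init_region)
      phi <- evolve(phi, sl, NULL, params)
      region <- phi < 0
      # past the kidney pole the region force alone cannot empty a large
      # contour within the iteration budget; a region whose mean intensity
      # falls below mu is background by the energy's own region model, so
      # treat it as vanished
      if (!any(region) || mean(sl[region]) < params$mu) break
      mask[, k, ] <- as.integer(region)
      prev <- region
      k <- k + dir
    }
  }
  kidney_mask(mask, side = side, grid_link = vol$source_id,
              spacing_inplane = vol$spacing_inplane,
              slice_thickness = vol$slice_thickness)
}
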