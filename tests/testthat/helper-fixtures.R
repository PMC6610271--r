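# Shared fixtures, built in code and memoised so expensive phantoms are
# rendered once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small two-kidney phantom with the default study degradations
fx_phantom_small <- function() fixture("small", function()
  phantom_generate(phantom_two_kidney_spec(
    tkv_ml = 500, seed = 301, n_cysts = 8, noise_sd = 3,
    interslice_gain_range = c(0.9, 1.1))))

# mid-size clean phantom (no cysts, no degradations)
fx_phantom_clean <- function() fixture("clean", function()
  phantom_generate(phantom_two_kidney_spec(tkv_ml = 1167, seed = 42)))

# bright disc on dark ground; the threshold-at-mu oracle is exact here
fx_disc <- function(n = 80, R = 20, inside = 120, outside = 10) {
  xx <- outer(seq_len(n), rep(1, n)); yy <- t(xx)
  r <- sqrt((xx - (n + 1) / 2)^2 + (yy - (n + 1) / 2)^2)
  img <- matrix(outside, n, n)
  img[r <= R] <- inside
  list(img = img, truth = r <= R, r = r, centre = (n + 1) / 2)
}

circle_seed <- function(centre, radius, slice_index = 1L, n_vertices = 32L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  seed_contour(slice_index, cbind(centre + radius * cos(t),
                                  centre + radius * sin(t)))
}

as_mask3d <- function(m) array(as.integer(m), dim = c(dim(m), 1L))

dice2d <- function(a, b) dice(as_mask3d(a), as_mask3d(b))

# coronal slice indices where a phantom's kidneys have substantial area
occupied_slices <- function(ph, min_area = 200) {
  tot <- Reduce(`+`, lapply(ph$masks, function(m) apply(m$voxels, 2, sum)))
  which(tot > min_area)
}

# the 30-case validation cohort (analytic TKV 258-3680 ml, 1.5 mm in-plane /
# 4 mm slices, cysts + noise + inter-slice gain drift), segmented by the
# full pipeline and scored against analytic truth; computed once per run
fx_cohort_results <- function() fixture("cohort", function() {
  specs <- phantom_cohort(30, c(258, 3680), seed = 101,
                          n_cysts = 12, noise_sd = 3,
                          interslice_gain_range = c(0.9, 1.1))
  rows <- lapply(specs, function(s) {
    ph <- phantom_generate(s)
    res <- suppressWarnings(run_phantom_case(ph))
    tkv_true <- sum(ph$analytic_ml)
    est <- c(ellipsoid = 0, midslice = 0)
    for (i in seq_along(ph$masks)) {
      ext <- tkvtools:::mask_extents_mm(ph$masks[[i]])
      est["ellipsoid"] <- est["ellipsoid"] +
        ellipsoid_volume(ext["length_mm"], ext["width_mm"], ext["depth_mm"])
      mi <- tkvtools:::mask_midslice_input(ph$masks[[i]])
      est["midslice"] <- est["midslice"] +
        midslice_volume(mi$mid_slice_area_mm2, mi$n_slices,
                        mi$slice_thickness_mm)
    }
    data.frame(tkv_true = tkv_true,
               tkv_levelset = res$tkv_measured_ml,
               err_levelset_pct = res$tkv_error_pct,
               err_ellipsoid_pct = 100 * (est["ellipsoid"] - tkv_true) / tkv_true,
               err_midslice_pct = 100 * (est["midslice"] - tkv_true) / tkv_true,
               dsc_min = min(res$dsc), row.names = NULL)
  })
  do.call(rbind, rows)
})
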