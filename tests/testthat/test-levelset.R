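test_that("edge map is 1 on flat images and dips monotonically at edges", {
  g <- edge_map(matrix(42, 30, 30))
  expect_equal(g, matrix(1, 30, 30), tolerance = 1e-12)
  # 1D step profile: stronger edges or steeper slope constants deepen the dip
  step_img <- function(h) {
    m <- matrix(0, 40, 40); m[, 21:40] <- h; m
  }
  mins_h <- vapply(c(20, 50, 100, 200), function(h) min(edge_map(step_img(h))),
                   numeric(1))
  expect_true(all(diff(mins_h) < 0))
  mins_c <- vapply(c(0.1, 1, 5, 20), function(cc) min(edge_map(step_img(50), cc = cc)),
                   numeric(1))
  expect_true(all(diff(mins_c) < 0))
  expect_true(all(edge_map(step_img(50)) > 0))
  expect_true(all(edge_map(step_img(50)) <= 1))
})

test_that("edge map attains its minimum on the object boundary band", {
  d <- fx_disc()
  g <- edge_map(d$img)
  wh <- which(g == min(g), arr.ind = TRUE)
  r_at_min <- d$r[wh]
  expect_true(all(abs(r_at_min - 20) <= 2))
})

test_that("init_phi is a signed distance negative inside the seed polygon", {
  side <- 20
  pts <- rbind(c(30, 30), c(30, 30 + side), c(30 + side, 30 + side),
               c(30 + side, 30))
  phi <- init_phi(seed_contour(1, pts), c(80, 80))
  centre <- phi[40, 40]
  expect_lt(abs(centre - (-side / 2)), 1.5)
  # sign changes at the boundary within a voxel
  expect_gt(phi[30 - 2, 40], 0)
  expect_lt(phi[30 + 2, 40], 0)
  # rasterised interior area matches the polygon area within 2%
  expect_lt(abs(sum(phi < 0) - side^2) / side^2, 0.02)
  expect_error(init_phi(seed_contour(1, pts), c(20, 20)), "outside")
  expect_error(seed_contour(1, rbind(c(1, 1), c(2, 2), c(3, 3))), "degenerate|area")
  expect_error(seed_contour(1, rbind(c(0, 0), c(10, 6), c(10, 0), c(0, 8))),
               "self-intersecting")
})

test_that("region force grows bright interiors and shrinks dark ones", {
  n <- 80
  seed <- circle_seed((n + 1) / 2, 8)
  p <- levelset_params(beta = 0.5)
  phi0 <- init_phi(seed, c(n, n))
  a0 <- sum(phi0 < 0)
  bright <- matrix(100, n, n)
  areas <- numeric(0)
  phi <- phi0
  for (chunk in 1:5) {
    phi <- evolve(phi, bright, NULL, tkvtools::levelset_params(
      beta = 0.5, iterations = 20))
    areas <- c(areas, sum(phi < 0))
  }
  expect_true(all(diff(c(a0, areas)) >= 0))
  expect_gt(tail(areas, 1), a0)
  dark <- matrix(10, n, n)
  phi_d <- evolve(phi0, dark, NULL, levelset_params(beta = 0.5, iterations = 300))
  expect_equal(sum(phi_d < 0), 0)
})

test_that("pure curvature flow never grows the interface", {
  n <- 60
  phi0 <- init_phi(circle_seed((n + 1) / 2, 12), c(n, n))
  uniform <- matrix(100, n, n)
  p <- levelset_params(alpha = 1e-9, beta = 1000, iterations = 100)
  phi <- evolve(phi0, uniform, NULL, p)
  expect_lte(sum(phi < 0), sum(phi0 < 0))
})

test_that("bright disc converges to the threshold oracle at the default parameters", {
  d <- fx_disc()
  # oracle: threshold at mu, exact for a two-level image
  oracle <- d$img > 50
  for (scale in c(0.8, 1.1)) {
    phi <- evolve(init_phi(circle_seed(d$centre, scale * 20), c(80, 80)),
                  d$img, NULL, levelset_params())
    expect_gte(dice2d(phi < 0, oracle), 0.95)
  }
})

test_that("evolution is deterministic", {
  d <- fx_disc()
  run <- function() evolve(init_phi(circle_seed(d$centre, 16), c(80, 80)),
                           d$img, NULL, levelset_params())
  expect_identical(run(), run())
})

test_that("a single-slice volume reduces segment_kidney to evolve", {
  d <- fx_disc()
  vol <- image_volume(array(d$img, c(80, 1, 80)), c(1, 1), 4)
  seed <- circle_seed(d$centre, 16, slice_index = 1L)
  m <- segment_kidney(vol, seed, side = "right", rescale = FALSE)
  phi <- evolve(init_phi(seed, c(80, 80)), d$img, NULL, levelset_params())
  expect_equal(m$voxels[, 1, ], matrix(as.integer(phi < 0), 80, 80))
  expect_equal(m$side, "right")
})

test_that("phantom kidney segments accurately with and without cysts", {
  ph <- fx_phantom_clean()
  res <- run_phantom_case(ph)
  expect_true(all(res$dsc >= 0.95))
  expect_lt(abs(res$tkv_error_pct), 3)

  phc <- fixture("cysts", function()
    phantom_generate(phantom_two_kidney_spec(tkv_ml = 1167, seed = 42,
                                             n_cysts = 20)))
  resc <- run_phantom_case(phc)
  expect_true(all(resc$dsc >= 0.93))
  # cysts are hyperintense kidney tissue: the mask must cover them
  for (i in 1:2) {
    side <- phc$masks[[i]]$side
    cys <- phc$cysts[phc$cysts$kidney == i, ]
    vx <- resc$masks[[side]]$voxels
    for (j in seq_len(nrow(cys))) {
      cv <- round(tkvtools:::phantom_mm_to_voxel(
        phc, c(cys$x_mm[j], cys$y_mm[j], cys$z_mm[j])))
      expect_equal(vx[cv[1], cv[2], cv[3]], 1L)
    }
  }
})

test_that("segmentation is insensitive to seed placement within +-3 voxels", {
  ph <- fx_phantom_small()
  off <- 3 * 1.5 / sqrt(prod(ph$spec$kidneys[[1]]$semiaxes[c(1, 3)]))
  r_in <- run_phantom_case(ph, seed_scale = 1 - off)
  r_out <- run_phantom_case(ph, seed_scale = 1 + off)
  expect_gte(dice(r_in$masks$right, r_out$masks$right), 0.99)
  expect_gte(dice(r_in$masks$left, r_out$masks$left), 0.99)
})

test_that("the 100-iteration stopping rule is near convergence", {
  ph <- fx_phantom_small()
  r100 <- run_phantom_case(ph)
  r200 <- run_phantom_case(ph, params = levelset_params(iterations = 200))
  expect_gte(dice(r100$masks$right, r200$masks$right), 0.98)
  expect_gte(dice(r100$masks$left, r200$masks$left), 0.98)
})

test_that("segment_kidney validates its inputs", {
  d <- fx_disc()
  vol <- image_volume(array(d$img, c(80, 1, 80)), c(1, 1), 4)
  expect_error(segment_kidney(vol, circle_seed(d$centre, 16, slice_index = 5L)),
               "outside")
  dark <- image_volume(array(10, c(40, 1, 40)), c(1, 1), 4)
  expect_error(segment_kidney(dark, circle_seed(20, 8, 1L),
                              params = levelset_params(beta = 0.5),
                              rescale = FALSE),
               "empty mid-slice")
})
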