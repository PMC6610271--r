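test_that("dice handles the canonical cases and is symmetric", {
  a <- array(0L, c(10, 2, 10)); a[1:5, 1, 1:10] <- 1L
  b <- array(0L, c(10, 2, 10)); b[1:5, 1, 1:10] <- 1L
  expect_equal(dice(a, b), 1)
  disj <- array(0L, c(10, 2, 10)); disj[6:10, 2, 1:10] <- 1L
  expect_equal(dice(a, disj), 0)
  # |A| = |B| = 100, |A n B| = 50
  a2 <- array(0L, c(20, 1, 20)); a2[1:10, 1, 1:10] <- 1L
  b2 <- array(0L, c(20, 1, 20)); b2[6:15, 1, 1:10] <- 1L
  expect_equal(sum(a2), 100); expect_equal(sum(b2), 100)
  expect_equal(sum(a2 * b2), 50)
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(a2, b2), dice(b2, a2))
  expect_equal(dice(array(0L, c(3, 3, 3)), array(0L, c(3, 3, 3))), 1)
  expect_error(dice(a, array(0L, c(9, 2, 10))), "mismatch")
})

test_that("bland_altman computes bias, SD and limits of agreement", {
  self <- bland_altman(c(100, 200, 300), c(100, 200, 300))
  expect_equal(self$bias, 0); expect_equal(self$sd_diff, 0)
  pct <- bland_altman(c(100, 200), c(102, 204), mode = "percent")
  expect_equal(pct$bias, 2); expect_equal(pct$sd_diff, 0)
  expect_equal(pct$loa_low, 2); expect_equal(pct$loa_high, 2)
  raw <- bland_altman(c(10, 20, 40), c(12, 19, 45))
  expect_equal(raw$loa_low, raw$bias - 1.96 * raw$sd_diff)
  expect_equal(raw$loa_high, raw$bias + 1.96 * raw$sd_diff)
  # antisymmetry under swapping reference and test
  swp <- bland_altman(c(12, 19, 45), c(10, 20, 40))
  expect_equal(swp$bias, -raw$bias)
  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(c(0, 1), c(1, 2), mode = "percent"), "positive")
})

test_that("bland_altman recovers known bias and SD from simulation", {
  set.seed(2024)
  ref <- exp(rnorm(1000, log(1000), 0.4))
  test <- ref * (1 + rnorm(1000, 0.02, 0.05))
  ba <- bland_altman(ref, test, mode = "percent")
  expect_lt(abs(ba$bias - 2), 0.5)
  expect_lt(abs(ba$sd_diff - 5), 0.5)
})

test_that("coefficient_of_variation matches hand computation and simulation", {
  expect_equal(coefficient_of_variation(c(100, 250), c(100, 250)), 0)
  # one subject, repeats (100, 102): SD = sqrt(2), mean = 101
  expect_equal(coefficient_of_variation(100, 102),
               100 * sqrt(2) / 101, tolerance = 1e-10)
  expect_lt(abs(coefficient_of_variation(100, 102) - 1.4), 0.1)
  set.seed(7)
  m <- exp(rnorm(500, log(1200), 0.3))
  r1 <- m * (1 + rnorm(500, 0, 0.02))
  r2 <- m * (1 + rnorm(500, 0, 0.02))
  # within-subject CoV of two repeats with per-measurement CoV 2%
  expect_lt(abs(coefficient_of_variation(r1, r2) - 2), 0.3)
  expect_error(coefficient_of_variation(c(-1, 2), c(1, 2)), "positive")
})

test_that("ba_sample_size reproduces its anchor and behaves monotonically", {
  expect_identical(ba_sample_size(2, 5, 15, 0.05, 0.80), 60L)
  # loose allowed difference collapses to a small study
  expect_lt(ba_sample_size(2, 5, 50, 0.05, 0.80), 10L)
  expect_gte(ba_sample_size(2, 5, 50, 0.05, 0.80), 2L)
  # doubling the SD (with the bound widened to stay feasible) raises n
  n1 <- ba_sample_size(2, 5, 30, 0.05, 0.80)
  n2 <- ba_sample_size(2, 10, 30, 0.05, 0.80)
  expect_gt(n2, n1)
  # tightening the bound raises n
  expect_gt(ba_sample_size(2, 5, 14, 0.05, 0.80),
            ba_sample_size(2, 5, 16, 0.05, 0.80))
  expect_error(ba_sample_size(2, 5, 11, 0.05, 0.80), "infeasible")
})

test_that("volume_error_table reproduces hand-computed differences", {
  ref <- data.frame(subject_id = c("a", "b"),
                    right_kv_ml = c(500, 600), left_kv_ml = c(550, 660))
  same <- volume_error_table(ref, list(self = ref))
  expect_true(all(same$pct_diff_mean == 0))
  expect_true(all(same$raw_diff_mean_ml == 0))
  tst <- data.frame(subject_id = c("b", "a"),  # shuffled on purpose
                    right_kv_ml = c(630, 490), left_kv_ml = c(693, 561))
  tab <- volume_error_table(ref, list(m = tst))
  right <- tab[tab$region == "right_kv", ]
  # a: 490 vs 500 -> -2%; b: 630 vs 600 -> +5%
  expect_equal(right$pct_diff_mean, mean(c(-2, 5)))
  expect_equal(right$raw_diff_mean_ml, mean(c(-10, 30)))
  tkv <- tab[tab$region == "tkv", ]
  expect_equal(tkv$raw_diff_mean_ml, mean(c(490 + 561 - 1050, 630 + 693 - 1260)))
  bad <- data.frame(subject_id = c("a", "z"),
                    right_kv_ml = 1:2, left_kv_ml = 1:2)
  expect_error(volume_error_table(ref, list(m = bad)), "unmatched")
})

test_that("bland_altman_plot returns a ggplot with bias and LoA lines", {
  ba <- bland_altman(c(100, 200, 300), c(104, 197, 311), mode = "percent")
  p <- bland_altman_plot(ba, title = "demo")
  expect_s3_class(p, "ggplot")
  expect_gte(length(p$layers), 3)
})
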