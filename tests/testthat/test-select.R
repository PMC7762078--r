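# Closed-form OLS oracle (textbook formulas), independent of stats::lm.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (sxx * syy))
}

as_img <- function(v) matrix(v, nrow = 1)

test_that("fluorescence binning uses equal-width bins with inclusive last edge", {
  fl <- as_img(0:9)
  mask <- pixel_mask(as_img(rep(TRUE, 10)))
  b <- bin_by_fluorescence(fl, mask, n_bins = 2)
  expect_equal(b$edges, c(0, 4.5, 9))
  expect_equal(sum(b$bin == 1, na.rm = TRUE), 5)  # 0..4
  expect_equal(sum(b$bin == 2, na.rm = TRUE), 5)  # 5..9 (right edge in bin 2)

  b1 <- bin_by_fluorescence(fl, mask, n_bins = 1)
  expect_true(all(b1$bin[mask] == 1))

  const <- bin_by_fluorescence(as_img(rep(3, 10)), mask, n_bins = 5)
  expect_true(all(const$bin[mask] == 1))

  expect_error(bin_by_fluorescence(fl, pixel_mask(as_img(rep(FALSE, 10)))),
               "empty")
})

test_that("SD-band selection keeps pixels within k_sd sample SDs per bin", {
  # all-identical bin: SD = 0, every pixel kept (inclusive boundary)
  g <- as_img(rep(5, 4)); fl <- as_img(rep(1, 4))
  mask <- pixel_mask(as_img(rep(TRUE, 4)))
  sel <- sd_band_select(g, fl, mask, n_bins = 1)
  expect_true(all(sel$mask))

  # {10, 10, 100}: mean 40, sample SD sqrt(2700) ~ 51.96; the outlier is out
  g <- as_img(c(10, 10, 100)); fl <- as_img(c(1, 1.1, 0.9))
  mask <- pixel_mask(as_img(rep(TRUE, 3)))
  sel <- sd_band_select(g, fl, mask, n_bins = 1, k_sd = 1)
  expect_equal(sel$stats$mean_green, 40)
  expect_equal(sel$stats$sd_green, sqrt(2700))
  expect_identical(c(sel$mask), c(TRUE, TRUE, FALSE))
  expect_equal(sel$stats$kept, 2L)
})

test_that("noise-free scenes keep every sub-saturation Bragg pixel (residual band)", {
  cfg <- tiny_config(noise_sd = 0, median_nm = 10, sigma_log = 0.25)
  sim <- simulate_timelapse(cfg)
  truth <- sim$truth$height_map$bragg_truth
  expect_true(max(sim$truth$height_map$h) < 30)  # all below saturation
  g0 <- sim$stack$frames[, , 2, 1]

  # residuals from the exact linear relation are all zero, so the residual
  # band retains 100% of the pixels
  sel_res <- sd_band_select(g0, sim$fluorescence, pixel_mask(truth),
                            n_bins = 8, method = "residual")
  expect_identical(as.vector(sel_res$mask), as.vector(truth))

  # the per-bin-mean band trims within-bin height extremes even without
  # noise (green varies within each fluorescence bin), but keeps a majority
  sel_bin <- sd_band_select(g0, sim$fluorescence, pixel_mask(truth),
                            n_bins = 8)
  expect_true(all(sel_bin$mask <= truth))
  expect_gt(sum(sel_bin$mask) / sum(truth), 0.5)
})

test_that("SD-band output is a subset of its input, and may shrink on rerun", {
  cfg <- tiny_config(noise_sd = 0.01, defect_fraction = 0.1,
                     defect_offset_sd = 0.15)
  sim <- simulate_timelapse(cfg)
  truth <- sim$truth$height_map$bragg_truth
  g0 <- mean_channel(sim$stack, baseline_frames(sim$stack, 2))
  sel1 <- sd_band_select(g0, sim$fluorescence, pixel_mask(truth))
  expect_true(all(sel1$mask <= truth))
  expect_lt(sum(sel1$mask), sum(truth))  # defects get rejected
  sel2 <- sd_band_select(g0, sim$fluorescence, sel1$mask)
  expect_true(all(sel2$mask <= sel1$mask))  # not claimed idempotent
})

test_that("under-occupied bins are dropped, and all-dropped is an error", {
  g <- as_img(c(1, 1, 1, 9))
  fl <- as_img(c(0, 0.1, 0.2, 10))  # lone pixel in the top bin
  mask <- pixel_mask(as_img(rep(TRUE, 4)))
  sel <- sd_band_select(g, fl, mask, n_bins = 2, min_bin_n = 3)
  expect_identical(c(sel$mask), c(TRUE, TRUE, TRUE, FALSE))

  expect_error(
    sd_band_select(as_img(1:2), as_img(1:2), pixel_mask(as_img(rep(TRUE, 2))),
                   n_bins = 1, min_bin_n = 3),
    "fewer bins"
  )
})

test_that("height-diffraction fit matches closed-form least squares", {
  # exact affine data
  fl <- matrix(runif(30, 0, 1), 5, 6)
  g <- 2 * fl + 3
  mask <- pixel_mask(matrix(TRUE, 5, 6))
  fit <- fit_height_diffraction(g, fl, mask)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_pixels, 30L)

  # hand-checkable three-point case, against the closed-form oracle
  fl <- as_img(c(1, 2, 3)); g <- as_img(c(1, 2, 4))
  fit <- fit_height_diffraction(g, fl, pixel_mask(as_img(rep(TRUE, 3))))
  oracle <- ols_oracle(c(1, 2, 3), c(1, 2, 4))
  expect_equal(fit$slope, oracle$slope)        # 3/2
  expect_equal(fit$intercept, oracle$intercept)
  expect_equal(fit$r_squared, oracle$r_squared)
  expect_equal(fit$r_squared, 27 / 28)

  expect_error(
    fit_height_diffraction(g, as_img(rep(1, 3)),
                           pixel_mask(as_img(rep(TRUE, 3)))),
    "constant"
  )
})

test_that("noise-free simulated scenes give a perfect linear fit", {
  cfg <- tiny_config(noise_sd = 0, median_nm = 10, sigma_log = 0.25)
  sim <- simulate_timelapse(cfg)
  truth <- sim$truth$height_map$bragg_truth
  expect_true(max(sim$truth$height_map$h) < 30)
  fit <- fit_height_diffraction(sim$stack$frames[, , 2, 1],
                                sim$fluorescence, pixel_mask(truth))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # slope recovers the gain ratio c_D / c_F exactly without noise
  expect_equal(fit$slope, cfg$optics$c_D / cfg$optics$c_F, tolerance = 1e-9)
})
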