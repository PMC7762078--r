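# Independent piecewise oracle for the height-diffraction law.
eff_oracle <- function(h, w, c_D) {
  vapply(h, function(hi) if (hi <= w / 10) c_D * hi else c_D * (w / 10),
         numeric(1))
}

test_that("diffraction efficiency is linear in height up to w/10, then capped", {
  expect_equal(diffraction_efficiency(0, 300, 1), 0)
  expect_equal(diffraction_efficiency(30, 300, 1), 30)
  expect_equal(diffraction_efficiency(60, 300, 1), 30)  # saturated
  expect_equal(diffraction_efficiency(15, 300, 2), eff_oracle(15, 300, 2))
  expect_equal(diffraction_efficiency(15, 300, 2), 30)

  h <- seq(0, 100, by = 0.5)
  eff <- diffraction_efficiency(h, 300, 1.7)
  expect_equal(eff, eff_oracle(h, 300, 1.7))
  expect_true(all(diff(eff) >= 0))                       # nondecreasing
  below <- h <= 30
  expect_equal(eff[below], 1.7 * h[below])               # exactly linear
  expect_true(all(eff[!below] == 1.7 * 30))              # constant above
})

test_that("diffraction efficiency rejects invalid inputs", {
  expect_error(diffraction_efficiency(-1, 300, 1))
  expect_error(diffraction_efficiency(NaN, 300, 1))
  expect_error(diffraction_efficiency(10, 0, 1))
  expect_error(diffraction_efficiency(10, 300, -0.1))
})

test_that("binding response follows pseudo-first-order saturation kinetics", {
  p <- binding_params(amplitude_A = 0.2, rate_k_per_min = 0.5)
  expect_equal(binding_response(c(0, 1, 4.999), t0 = 5, p), rep(0, 3))
  expect_equal(binding_response(5 + 1 / 0.5, t0 = 5, p),
               0.2 * (1 - exp(-1)))
  expect_equal(binding_response(1e6, t0 = 5, p), 0.2, tolerance = 1e-12)

  tt <- seq(0, 30, by = 0.1)
  r <- binding_response(tt, t0 = 5, p)
  expect_true(all(diff(r) >= 0))

  # height scaling: amplitude proportional to h/h_max, capped at 1
  ps <- binding_params(amplitude_A = 0.2, rate_k_per_min = 0.5,
                       height_scaling = TRUE)
  r_half <- binding_response(1e6, t0 = 0, ps, h = 15, h_max = 30)
  r_over <- binding_response(1e6, t0 = 0, ps, h = 60, h_max = 30)
  expect_equal(r_half, 0.1, tolerance = 1e-12)
  expect_equal(r_over, 0.2, tolerance = 1e-12)
})

test_that("fluorescence is affine in multilayer height", {
  cfg <- tiny_config(noise_sd = 0)
  sim <- simulate_timelapse(cfg)
  hm <- sim$truth$height_map
  op <- cfg$optics

  # h = 0 everywhere -> uniform background
  flat <- structure(list(h = matrix(0, 4, 4),
                         spot_label = matrix(0L, 4, 4),
                         bragg_truth = matrix(FALSE, 4, 4)),
                    class = "height_map")
  img <- render_fluorescence(flat, op, noise_sd = 0)
  expect_true(all(img == op$background_level))

  # doubling height doubles fluorescence when background is 0
  op0 <- optics_params(background_level = 0)
  two <- structure(list(h = matrix(c(10, 20), 1, 2),
                        spot_label = matrix(1L, 1, 2),
                        bragg_truth = matrix(TRUE, 1, 2)),
                   class = "height_map")
  f <- render_fluorescence(two, op0, noise_sd = 0)
  expect_equal(f[1, 2], 2 * f[1, 1])

  # exact affine relation: Pearson r = 1 on lognormal heights
  on_grating <- hm$bragg_truth
  expect_equal(cor(sim$fluorescence[on_grating], hm$h[on_grating]), 1)
})

test_that("diffraction frames compose the optical laws", {
  cfg <- tiny_config(noise_sd = 0, median_nm = 40, sigma_log = 0)  # saturated
  sim <- simulate_timelapse(cfg)
  op <- cfg$optics
  fr0 <- sim$stack$frames[, , , 1]
  hm <- sim$truth$height_map

  # saturated Bragg pixel before addition: green - background = c_D * w / 10
  g <- fr0[, , 2]
  expect_equal(unique(g[hm$bragg_truth]),
               op$background_level + op$c_D * 30)

  # scatter is color-neutral: green/red = 1
  sc <- sim$truth$scatter_mask
  expect_true(any(sc))
  expect_equal(fr0[, , 2][sc] / fr0[, , 1][sc], rep(1, sum(sc)))

  # Bragg pixels are green-dominant by the contrast factor (background 0)
  cfg0 <- tiny_config(noise_sd = 0, background_level = 0)
  sim0 <- simulate_timelapse(cfg0)
  fr <- sim0$stack$frames[, , , 1]
  bt <- sim0$truth$height_map$bragg_truth
  expect_equal(fr[, , 2][bt] / fr[, , 1][bt],
               rep(cfg0$optics$bragg_green_red_contrast, sum(bt)))
})

test_that("control spots are time-invariant without noise", {
  cfg <- tiny_config(noise_sd = 0, amplitude = 0)
  sim <- simulate_timelapse(cfg)
  first <- sim$stack$frames[, , , 1]
  last <- sim$stack$frames[, , , n_frames(sim$stack)]
  expect_identical(first, last)
})

test_that("time lapse has the right frame count, timestamps, and determinism", {
  cfg <- tiny_config(duration_min = 20, frame_rate_per_min = 5,
                     analyte_time_min = 5)
  sim <- simulate_timelapse(cfg)
  expect_equal(n_frames(sim$stack), floor(20 * 5) + 1)  # 101 frames
  expect_equal(sim$stack$t_min, (0:100) / 5)

  sim2 <- simulate_timelapse(cfg)
  expect_identical(sim$stack$frames, sim2$stack$frames)
  expect_identical(sim$fluorescence, sim2$fluorescence)
  expect_identical(sim$truth, sim2$truth)

  # a different seed changes the scene
  sim3 <- simulate_timelapse(cfg, seed = 999)
  expect_false(identical(sim$stack$frames, sim3$stack$frames))

  # caller RNG state is preserved
  set.seed(123); before <- .Random.seed
  invisible(simulate_timelapse(cfg))
  expect_identical(before, .Random.seed)
})

test_that("ground truth is internally consistent", {
  cfg <- tiny_config(noise_sd = 0.01, defect_fraction = 0.1,
                     defect_offset_sd = 0.1, defect_noise_sd = 0.05)
  sim <- simulate_timelapse(cfg)
  hm <- sim$truth$height_map
  expect_true(all(hm$h[!hm$bragg_truth] == 0))
  expect_true(all(hm$h[hm$bragg_truth] > 0))
  expect_false(any(sim$truth$scatter_mask & hm$bragg_truth))
  expect_true(all(hm$bragg_truth[sim$truth$defect_mask]))
})

test_that("empty and invalid configurations are handled", {
  cfg <- tiny_config()
  cfg$spots <- list()
  sim <- simulate_timelapse(cfg)
  expect_true(all(sim$truth$height_map$h == 0))

  expect_error(simulation_config(analyte_time_min = 25, duration_min = 20),
               "analyte_time_min")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(scatter_fraction = 2), "scatter_fraction")
})
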