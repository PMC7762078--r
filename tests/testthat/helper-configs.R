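# Small, fast simulation configs used across the test files.

# One 20x20 grating spot in a 40x60 field; optionally a second control spot.
tiny_config <- function(noise_sd = 0,
                        amplitude = 0.2,
                        rate_k = 0.5,
                        height_scaling = FALSE,
                        median_nm = 14,
                        sigma_log = 0.3,
                        scatter_fraction = 0.1,
                        defect_fraction = 0,
                        defect_offset_sd = 0,
                        defect_noise_sd = 0,
                        background_level = 0.01,
                        duration_min = 6,
                        analyte_time_min = 2,
                        frame_rate_per_min = 5,
                        two_spots = FALSE,
                        seed = 1L) {
  spots <- list(spot_spec(
    region = list(type = "rect", row = c(5, 24), col = c(5, 24)),
    median_nm = median_nm, sigma_log = sigma_log,
    functionalized = amplitude > 0,
    response = binding_params(amplitude_A = amplitude,
                              rate_k_per_min = rate_k,
                              height_scaling = height_scaling),
    label = "aptamer"
  ))
  if (two_spots) {
    spots <- c(spots, list(spot_spec(
      region = list(type = "rect", row = c(5, 24), col = c(35, 54)),
      median_nm = median_nm, sigma_log = sigma_log,
      functionalized = FALSE,
      response = binding_params(amplitude_A = 0, rate_k_per_min = rate_k),
      label = "control"
    )))
  }
  simulation_config(
    image_shape = c(40L, 60L),
    line_width_nm = 300,
    frame_rate_per_min = frame_rate_per_min,
    duration_min = duration_min,
    analyte_time_min = analyte_time_min,
    spots = spots,
    optics = optics_params(background_level = background_level),
    noise_sd = noise_sd,
    scatter_fraction = scatter_fraction,
    defect_fraction = defect_fraction,
    defect_offset_sd = defect_offset_sd,
    defect_noise_sd = defect_noise_sd,
    seed = seed
  )
}

# ROI list (named by spot label) from a simulation config.
spot_rois <- function(cfg) {
  rois <- lapply(cfg$spots, function(s) s$region)
  names(rois) <- vapply(cfg$spots, function(s) s$label, character(1))
  rois
}
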