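#' Optical parameters of the forward model
#'
#' Bundles the coefficients that map multilayer height to recorded intensity.
#' All intensities are dimensionless arbitrary units (a.u.) in `[0, 1]`;
#' quantization to 16 bits happens only when images are written to disk.
#'
#' @param c_F Fluorescence gain, a.u. per nm of multilayer height. The dye is
#'   distributed through the lipid volume, so fluorescence is proportional to
#'   local thickness and serves as the height proxy.
#' @param c_D Green diffraction gain, a.u. per nm of height, valid below the
#'   saturation height (one tenth of the grating line width).
#' @param bragg_green_red_contrast Factor by which a Bragg pixel's diffracted
#'   green signal exceeds the light leaking into the red (and blue) channel.
#'   Must be > 1; this is what makes green:red ratio classification work.
#' @param background_level Additive background, a.u. Oblique illumination
#'   means only diffracted or scattered light reaches the objective, so the
#'   default is near-dark.
#' @param scatter_level_range Length-2 interval, a.u., from which the
#'   (color-neutral) intensity of broadband scatter pixels is drawn.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(c_F = 0.02,
                          c_D = 0.018,
                          bragg_green_red_contrast = 4,
                          background_level = 0.01,
                          scatter_level_range = c(0.2, 0.6)) {
  stopifnot(
    is.numeric(c_F), c_F >= 0,
    is.numeric(c_D), c_D >= 0,
    is.numeric(bragg_green_red_contrast), bragg_green_red_contrast > 1,
    is.numeric(background_level), background_level >= 0,
    length(scatter_level_range) == 2, all(scatter_level_range >= 0),
    scatter_level_range[1] <= scatter_level_range[2]
  )
  structure(
    list(
      c_F = c_F, c_D = c_D,
      bragg_green_red_contrast = bragg_green_red_contrast,
      background_level = background_level,
      scatter_level_range = scatter_level_range
    ),
    class = "optics_params"
  )
}

#' Analyte binding response parameters
#'
#' Pseudo-first-order saturation kinetics for the fractional increase in
#' diffracted green intensity after analyte addition. Control gratings carry
#' `amplitude_A = 0`.
#'
#' @param amplitude_A Steady-state fractional increase (dimensionless) for a
#'   full-height grating; e.g. `0.2` is a 20 percent increase at saturation.
#' @param rate_k_per_min Approach rate in 1/min.
#' @param height_scaling If `TRUE`, the effective amplitude is
#'   `amplitude_A * min(h / h_max, 1)`, so taller gratings respond more.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(amplitude_A = 0,
                           rate_k_per_min = 0.5,
                           height_scaling = FALSE) {
  stopifnot(
    is.numeric(amplitude_A), amplitude_A >= 0,
    is.numeric(rate_k_per_min), rate_k_per_min > 0,
    is.logical(height_scaling), length(height_scaling) == 1
  )
  structure(
    list(
      amplitude_A = amplitude_A,
      rate_k_per_min = rate_k_per_min,
      height_scaling = height_scaling
    ),
    class = "binding_params"
  )
}

#' Specification of one printed grating spot
#'
#' @param region A list describing the pixel footprint, either
#'   `list(type = "rect", row = c(r0, r1), col = c(c0, c1))` (1-based,
#'   inclusive) or `list(type = "disk", center = c(r, c), radius = px)`.
#' @param median_nm Median multilayer height, nm. Per-pixel heights are drawn
#'   lognormal: heights are positive and right-skewed because they derive
#'   from the variable amount of ink transferred from the stamp.
#' @param sigma_log Log-scale standard deviation of the height distribution.
#' @param functionalized Logical; whether the grating carries the aptamer.
#' @param response A [binding_params()] object; controls must have amplitude 0.
#' @param label Sample identifier carried through to sensorgrams.
#' @param composition Optional free-text lipid composition metadata.
#' @return An object of class `spot_spec`.
#' @export
spot_spec <- function(region,
                      median_nm,
                      sigma_log = 0.35,
                      functionalized = FALSE,
                      response = binding_params(),
                      label = NULL,
                      composition = NULL) {
  stopifnot(
    is.list(region), !is.null(region$type),
    region$type %in% c("rect", "disk"),
    is.numeric(median_nm), median_nm > 0,
    is.numeric(sigma_log), sigma_log >= 0,
    inherits(response, "binding_params")
  )
  if (!functionalized && response$amplitude_A != 0) {
    stop("control (non-functionalized) spots must have amplitude_A = 0")
  }
  structure(
    list(
      region = region, median_nm = median_nm, sigma_log = sigma_log,
      functionalized = functionalized, response = response,
      label = label, composition = composition
    ),
    class = "spot_spec"
  )
}

#' Full simulation configuration
#'
#' @param image_shape Integer `(rows, cols)` of the simulated field of view.
#' @param line_width_nm Grating line width `w` in nm. The diffraction
#'   efficiency saturates at height `w / 10`.
#' @param frame_rate_per_min Acquisition rate, frames per minute.
#' @param duration_min Total recording time in minutes.
#' @param analyte_time_min Time at which the analyte is introduced, minutes
#'   from acquisition start; must lie strictly inside the recording.
#' @param spots List of [spot_spec()] objects.
#' @param optics An [optics_params()] object.
#' @param noise_sd Additive Gaussian camera-noise SD per channel per frame,
#'   a.u.; images are clipped at zero.
#' @param scatter_fraction Fraction of background pixels carrying broadband
#'   (color-neutral) scatter from dust and surface defects.
#' @param defect_fraction Fraction of grating pixels that are "defective":
#'   their green intensity sits off the linear height-diffraction relation by
#'   a static offset and fluctuates with extra temporal noise, emulating
#'   unstable fluid grating regions. Zero by default.
#' @param defect_offset_sd SD of the static green-intensity offset of defect
#'   pixels, a.u.
#' @param defect_noise_sd Extra temporal noise SD on defect pixels' green
#'   channel, a.u.
#' @param seed Integer RNG seed; all randomness in a simulation flows from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(image_shape = c(96L, 128L),
                              line_width_nm = 300,
                              frame_rate_per_min = 5,
                              duration_min = 20,
                              analyte_time_min = 5,
                              spots = list(),
                              optics = optics_params(),
                              noise_sd = 0.01,
                              scatter_fraction = 0.05,
                              defect_fraction = 0,
                              defect_offset_sd = 0,
                              defect_noise_sd = 0,
                              seed = 1L) {
  cfg <- structure(
    list(
      image_shape = as.integer(image_shape),
      line_width_nm = line_width_nm,
      frame_rate_per_min = frame_rate_per_min,
      duration_min = duration_min,
      analyte_time_min = analyte_time_min,
      spots = spots,
      optics = optics,
      noise_sd = noise_sd,
      scatter_fraction = scatter_fraction,
      defect_fraction = defect_fraction,
      defect_offset_sd = defect_offset_sd,
      defect_noise_sd = defect_noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
  problems <- validate_simulation_config(cfg)
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `simulation_config`.
#' @return Character vector of problems (empty when valid).
#' @export
validate_simulation_config <- function(config) {
  p <- character()
  if (length(config$image_shape) != 2 || any(config$image_shape < 1)) {
    p <- c(p, "image_shape must be two positive integers")
  }
  if (!is.numeric(config$line_width_nm) || config$line_width_nm <= 0) {
    p <- c(p, "line_width_nm must be > 0")
  }
  if (!is.numeric(config$frame_rate_per_min) || config$frame_rate_per_min <= 0) {
    p <- c(p, "frame_rate_per_min must be > 0")
  }
  if (!is.numeric(config$duration_min) || config$duration_min <= 0) {
    p <- c(p, "duration_min must be > 0")
  }
  if (!is.numeric(config$analyte_time_min) ||
      config$analyte_time_min <= 0 ||
      config$analyte_time_min >= config$duration_min) {
    p <- c(p, "analyte_time_min must satisfy 0 < analyte_time_min < duration_min")
  }
  if (!is.numeric(config$noise_sd) || config$noise_sd < 0) {
    p <- c(p, "noise_sd must be >= 0")
  }
  if (!is.numeric(config$scatter_fraction) ||
      config$scatter_fraction < 0 || config$scatter_fraction > 1) {
    p <- c(p, "scatter_fraction must be in [0, 1]")
  }
  if (!is.numeric(config$defect_fraction) ||
      config$defect_fraction < 0 || config$defect_fraction > 1) {
    p <- c(p, "defect_fraction must be in [0, 1]")
  }
  if (!inherits(config$optics, "optics_params")) {
    p <- c(p, "optics must be an optics_params object")
  }
  if (length(config$spots) &&
      !all(vapply(config$spots, inherits, logical(1), "spot_spec"))) {
    p <- c(p, "spots must all be spot_spec objects")
  }
  p
}

#' Diffraction efficiency as a function of grating height
#'
#' Diffracted green intensity is linear in multilayer height up to a
#' saturation height of one tenth of the grating line width, then constant:
#' `c_D * min(h, w / 10)`.
#'
#' @param h Height(s), nm; non-negative.
#' @param w Grating line width, nm; positive.
#' @param c_D Diffraction gain, a.u. per nm.
#' @return Diffracted intensity, a.u., same shape as `h`.
#' @export
diffraction_efficiency <- function(h, w, c_D) {
  if (!all(is.finite(h)) || any(h < 0)) {
    stop("h must be finite and >= 0")
  }
  if (!is.finite(w) || w <= 0) stop("w must be finite and > 0")
  if (!is.finite(c_D) || c_D < 0) stop("c_D must be finite and >= 0")
  c_D * pmin(h, w / 10)
}

#' Fractional binding response at time t
#'
#' Pseudo-first-order saturation: zero before the analyte is added, then
#' `A_eff * (1 - exp(-k * (t - t0)))`, where `A_eff` scales with height
#' (capped at the saturation height) when `height_scaling` is on.
#'
#' @param t Time(s), minutes from acquisition start.
#' @param t0 Analyte addition time, minutes.
#' @param params A [binding_params()] object.
#' @param h Grating height(s), nm; only used when `height_scaling` is on.
#' @param h_max Saturation height (`w / 10`), nm.
#' @return Dimensionless fractional increase, same shape as `t` (or `h`).
#' @export
binding_response <- function(t, t0, params, h = h_max, h_max = 30) {
  stopifnot(all(t >= 0), inherits(params, "binding_params"))
  A_eff <- if (params$height_scaling) {
    params$amplitude_A * pmin(h / h_max, 1)
  } else {
    params$amplitude_A
  }
  ifelse(t < t0, 0, A_eff * (1 - exp(-params$rate_k_per_min * (t - t0))))
}

#' Logical footprint of a region spec on the image grid
#'
#' Regions are 1-based (row, col) rectangles or disks, the same specs used
#' for [spot_spec()] footprints and analysis ROIs.
#'
#' @param region `list(type = "rect", row = c(r0, r1), col = c(c0, c1))` or
#'   `list(type = "disk", center = c(r, c), radius = px)`.
#' @param shape Image shape `(rows, cols)`.
#' @return Logical matrix.
#' @export
region_mask <- function(region, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (region$type == "rect") {
    r <- region$row
    cl <- region$col
    stopifnot(r[1] >= 1, r[2] <= shape[1], cl[1] >= 1, cl[2] <= shape[2])
    m[r[1]:r[2], cl[1]:cl[2]] <- TRUE
  } else {
    rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    m <- (rr - region$center[1])^2 + (cc - region$center[2])^2 <=
      region$radius^2
  }
  m
}

# Draw the static scene: per-pixel heights, spot labels, scatter pixels and
# their levels, defect pixels and their offsets. Consumes the current RNG.
build_scene <- function(config) {
  shape <- config$image_shape
  h <- matrix(0, shape[1], shape[2])
  spot_label <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(config$spots)) {
    sp <- config$spots[[i]]
    m <- region_mask(sp$region, shape)
    if (any(spot_label[m] != 0L)) stop("spot regions overlap")
    n <- sum(m)
    h[m] <- stats::rlnorm(n, meanlog = log(sp$median_nm), sdlog = sp$sigma_log)
    spot_label[m] <- i
  }
  bragg_truth <- spot_label != 0L

  scatter_mask <- matrix(FALSE, shape[1], shape[2])
  bg_idx <- which(!bragg_truth)
  n_scatter <- round(config$scatter_fraction * length(bg_idx))
  if (n_scatter > 0) {
    scatter_mask[sample(bg_idx, n_scatter)] <- TRUE
  }
  scatter_level <- matrix(0, shape[1], shape[2])
  rng <- config$optics$scatter_level_range
  scatter_level[scatter_mask] <- stats::runif(sum(scatter_mask), rng[1], rng[2])

  defect_mask <- matrix(FALSE, shape[1], shape[2])
  defect_offset <- matrix(0, shape[1], shape[2])
  gr_idx <- which(bragg_truth)
  n_def <- round(config$defect_fraction * length(gr_idx))
  if (n_def > 0) {
    defect_mask[sample(gr_idx, n_def)] <- TRUE
    defect_offset[defect_mask] <- stats::rnorm(n_def, 0, config$defect_offset_sd)
  }

  height_map <- structure(
    list(h = h, spot_label = spot_label, bragg_truth = bragg_truth),
    class = "height_map"
  )
  structure(
    list(
      height_map = height_map,
      injected_amplitudes = vapply(
        config$spots, function(s) s$response$amplitude_A, numeric(1)
      ),
      scatter_mask = scatter_mask,
      scatter_level = scatter_level,
      defect_mask = defect_mask,
      defect_offset = defect_offset
    ),
    class = "ground_truth"
  )
}

#' Render the fluorescence (height proxy) image
#'
#' Pixel value is `c_F * h + background_level` plus Gaussian camera noise,
#' clipped at zero. With `noise_sd = 0` the image is an exact affine function
#' of height, which is what justifies using fluorescence to bin pixels by
#' grating height.
#'
#' @param height_map A `height_map` (from [simulate_timelapse()]'s ground
#'   truth, or built directly).
#' @param optics An [optics_params()] object.
#' @param noise_sd Gaussian noise SD, a.u.
#' @return Single-channel matrix, a.u.
#' @export
render_fluorescence <- function(height_map, optics, noise_sd = 0) {
  img <- optics$c_F * height_map$h + optics$background_level
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  pmax(img, 0)
}

#' Render one RGB diffraction frame
#'
#' Bragg (grating) pixels diffract green: the green channel carries
#' `diffraction_efficiency(h) * (1 + binding_response(t))` over background,
#' while red and blue receive that signal attenuated by the green:red
#' contrast factor. Broadband scatter pixels are color-neutral (all three
#' channels share one draw). Defect pixels additionally carry their static
#' green offset and extra temporal noise. Everything is clipped at zero.
#'
#' @param scene A `ground_truth` scene (height map plus scatter/defect maps).
#' @param config The `simulation_config`.
#' @param t Frame time, minutes from acquisition start.
#' @return `rows x cols x 3` array (R, G, B), a.u.
#' @export
render_diffraction_frame <- function(scene, config, t) {
  hm <- scene$height_map
  op <- config$optics
  shape <- config$image_shape
  h_max <- config$line_width_nm / 10

  D <- diffraction_efficiency(hm$h, config$line_width_nm, op$c_D)
  resp <- matrix(0, shape[1], shape[2])
  for (i in seq_along(config$spots)) {
    idx <- hm$spot_label == i
    if (!any(idx)) next
    resp[idx] <- binding_response(
      t, config$analyte_time_min, config$spots[[i]]$response,
      h = hm$h[idx], h_max = h_max
    )
  }
  signal <- D * (1 + resp)
  leak <- signal / op$bragg_green_red_contrast

  green <- op$background_level + signal + scene$defect_offset
  red <- op$background_level + leak
  blue <- op$background_level + leak

  sc <- scene$scatter_mask
  green[sc] <- scene$scatter_level[sc]
  red[sc] <- scene$scatter_level[sc]
  blue[sc] <- scene$scatter_level[sc]

  if (config$noise_sd > 0) {
    n <- length(green)
    green <- green + stats::rnorm(n, 0, config$noise_sd)
    red <- red + stats::rnorm(n, 0, config$noise_sd)
    blue <- blue + stats::rnorm(n, 0, config$noise_sd)
  }
  if (config$defect_noise_sd > 0 && any(scene$defect_mask)) {
    dm <- scene$defect_mask
    green[dm] <- green[dm] + stats::rnorm(sum(dm), 0, config$defect_noise_sd)
  }

  frame <- array(0, dim = c(shape[1], shape[2], 3))
  frame[, , 1] <- pmax(red, 0)
  frame[, , 2] <- pmax(green, 0)
  frame[, , 3] <- pmax(blue, 0)
  frame
}

#' Simulate a full diffraction time lapse with ground truth
#'
#' Draws the static scene (heights, scatter, defects), renders the
#' fluorescence image, then renders `floor(duration * rate) + 1` RGB frames
#' at evenly spaced times from 0 to the duration. The same configuration and
#' seed always reproduce bit-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `grating_simulation` with elements `stack` (an
#'   [image_stack()]), `fluorescence` (matrix), and `truth` (`ground_truth`).
#' @export
simulate_timelapse <- function(config, seed = config$seed) {
  problems <- validate_simulation_config(config)
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  scene <- build_scene(config)
  fluor <- render_fluorescence(scene$height_map, config$optics, config$noise_sd)

  n_frames <- floor(config$duration_min * config$frame_rate_per_min) + 1L
  t_min <- (seq_len(n_frames) - 1) / config$frame_rate_per_min
  shape <- config$image_shape
  frames <- array(0, dim = c(shape[1], shape[2], 3, n_frames))
  for (f in seq_len(n_frames)) {
    frames[, , , f] <- render_diffraction_frame(scene, config, t_min[f])
  }

  structure(
    list(
      stack = image_stack(frames, t_min),
      fluorescence = fluor,
      truth = scene,
      config = config
    ),
    class = "grating_simulation"
  )
}

#' Time-ordered RGB image stack
#'
#' @param frames `rows x cols x 3 x n_frames` numeric array (R, G, B order on
#'   the third axis), intensities in a.u.
#' @param t_min Strictly increasing frame timestamps, minutes from
#'   acquisition start.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, t_min) {
  stopifnot(
    length(dim(frames)) == 4, dim(frames)[3] == 3,
    length(t_min) == dim(frames)[4],
    all(diff(t_min) > 0)
  )
  structure(list(frames = frames, t_min = t_min), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d x %d px, %d RGB frames, t = %.2f..%.2f min\n",
    d[1], d[2], d[4], min(x$t_min), max(x$t_min)
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An `image_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[4]

#' Extract one channel of one frame
#' @param stack An `image_stack`.
#' @param frame Frame index (1-based).
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return Single-channel matrix.
#' @export
get_channel <- function(stack, frame, channel = c("green", "red", "blue")) {
  channel <- match.arg(channel)
  ch <- c(red = 1L, green = 2L, blue = 3L)[[channel]]
  stack$frames[, , ch, frame]
}

#' Indices of pre-addition (baseline) frames
#' @param stack An `image_stack`.
#' @param analyte_time_min Analyte addition time, minutes.
#' @return Integer vector of frame indices with `t < analyte_time_min`.
#' @export
baseline_frames <- function(stack, analyte_time_min) {
  which(stack$t_min < analyte_time_min)
}

#' Mean channel image over a window of frames
#'
#' The "initial" image used for ratio computation and SD-band selection is
#' the mean of all pre-addition frames, which averages down camera noise
#' relative to using frame 1 alone.
#'
#' @param stack An `image_stack`.
#' @param frames Frame indices to average.
#' @param channel Channel name.
#' @return Single-channel matrix.
#' @export
mean_channel <- function(stack, frames, channel = "green") {
  ch <- c(red = 1L, green = 2L, blue = 3L)[[match.arg(channel, c("green", "red", "blue"))]]
  sub <- stack$frames[, , ch, frames, drop = FALSE]
  apply(sub, c(1, 2), mean)
}
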