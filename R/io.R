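#' Write an RGB stack as a 16-bit multi-page TIFF with a timing sidecar
#'
#' Intensities are clipped to `[0, 1]` and quantized to 16 bits at write
#' time; frame times (minutes) go to a JSON sidecar at `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(n_frames(stack)), function(f) {
    pmin(pmax(stack$frames[, , , f], 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(t_min = stack$t_min), paste0(path, ".json"),
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read an RGB stack from a multi-page TIFF
#'
#' Intensities come back in `[0, 1]` (scaled from the file's bit depth by the
#' TIFF reader). Frame times are taken from the `<path>.json` sidecar when
#' present, else from `t_min`, else computed from `frame_rate_per_min`.
#'
#' @param path TIFF path.
#' @param t_min Optional explicit frame times, minutes.
#' @param frame_rate_per_min Optional frame rate used to synthesize times
#'   when no sidecar or explicit times exist.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, t_min = NULL, frame_rate_per_min = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, integer(1)) != 3) ||
      any(vapply(dims, function(d) d[3], numeric(1)) != 3)) {
    stop("expected an RGB (3-channel) stack: ", path)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("stack pages have mixed shapes: ", path)
  }
  nf <- length(pages)
  d <- dims[[1]]
  frames <- array(0, dim = c(d[1], d[2], 3, nf))
  for (f in seq_len(nf)) frames[, , , f] <- pages[[f]]

  sidecar <- paste0(path, ".json")
  if (is.null(t_min)) {
    if (file.exists(sidecar)) {
      t_min <- as.numeric(jsonlite::read_json(sidecar,
                                              simplifyVector = TRUE)$t_min)
    } else if (!is.null(frame_rate_per_min)) {
      t_min <- (seq_len(nf) - 1) / frame_rate_per_min
    } else {
      stop("no timing metadata: provide t_min, frame_rate_per_min, ",
           "or a ", sidecar, " sidecar")
    }
  }
  image_stack(frames, t_min)
}

#' Write a single-channel image as a 16-bit TIFF
#' @param img Numeric matrix in a.u. (clipped to `[0, 1]` at write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16)
  invisible(path)
}

#' Read a single-channel TIFF image
#' @param path TIFF path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 2) stop("expected a single-channel image: ", path)
  img
}

#' Write simulation ground truth as sidecar JSON plus a label TIFF
#'
#' The JSON carries per-spot injected amplitudes and pixel counts; the
#' multi-page label TIFF carries (1) the spot-label map, (2) the Bragg-truth
#' mask, (3) the scatter mask, (4) the defect mask, each scaled so that
#' `round(page * 65535)` recovers the integer labels.
#'
#' @param truth A `ground_truth` from [simulate_timelapse()].
#' @param json_path,label_path Output paths.
#' @return `json_path`, invisibly.
#' @export
write_ground_truth <- function(truth, json_path, label_path) {
  hm <- truth$height_map
  jsonlite::write_json(
    list(
      injected_amplitudes = truth$injected_amplitudes,
      n_bragg = sum(hm$bragg_truth),
      n_scatter = sum(truth$scatter_mask),
      n_defect = sum(truth$defect_mask),
      height_nm_range = range(hm$h[hm$bragg_truth])
    ),
    json_path, auto_unbox = FALSE, digits = NA
  )
  pages <- list(
    hm$spot_label / 65535,
    (hm$bragg_truth * 1) / 65535,
    (truth$scatter_mask * 1) / 65535,
    (truth$defect_mask * 1) / 65535
  )
  tiff::writeTIFF(pages, label_path, bits.per.sample = 16)
  invisible(json_path)
}

# ---- simulation config YAML ------------------------------------------------

spot_to_list <- function(sp) {
  list(
    label = sp$label, composition = sp$composition,
    region = sp$region,
    median_nm = sp$median_nm, sigma_log = sp$sigma_log,
    functionalized = sp$functionalized,
    response = list(
      amplitude_A = sp$response$amplitude_A,
      rate_k_per_min = sp$response$rate_k_per_min,
      height_scaling = sp$response$height_scaling
    )
  )
}

spot_from_list <- function(x) {
  r <- x$response
  spot_spec(
    region = x$region,
    median_nm = x$median_nm,
    sigma_log = x$sigma_log,
    functionalized = isTRUE(x$functionalized),
    response = binding_params(
      amplitude_A = r$amplitude_A,
      rate_k_per_min = r$rate_k_per_min,
      height_scaling = isTRUE(r$height_scaling)
    ),
    label = x$label,
    composition = x$composition
  )
}

#' Write a simulation configuration to YAML
#' @param config A [simulation_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_simulation_config <- function(config, path) {
  x <- list(
    image_shape = config$image_shape,
    line_width_nm = config$line_width_nm,
    frame_rate_per_min = config$frame_rate_per_min,
    duration_min = config$duration_min,
    analyte_time_min = config$analyte_time_min,
    noise_sd = config$noise_sd,
    scatter_fraction = config$scatter_fraction,
    defect_fraction = config$defect_fraction,
    defect_offset_sd = config$defect_offset_sd,
    defect_noise_sd = config$defect_noise_sd,
    seed = config$seed,
    optics = unclass(config$optics),
    spots = lapply(config$spots, spot_to_list)
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#' @param path YAML path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  op <- x$optics
  simulation_config(
    image_shape = unlist(x$image_shape),
    line_width_nm = x$line_width_nm,
    frame_rate_per_min = x$frame_rate_per_min,
    duration_min = x$duration_min,
    analyte_time_min = x$analyte_time_min,
    spots = lapply(x$spots, spot_from_list),
    optics = optics_params(
      c_F = op$c_F, c_D = op$c_D,
      bragg_green_red_contrast = op$bragg_green_red_contrast,
      background_level = op$background_level,
      scatter_level_range = unlist(op$scatter_level_range)
    ),
    noise_sd = x$noise_sd,
    scatter_fraction = x$scatter_fraction,
    defect_fraction = x$defect_fraction %||% 0,
    defect_offset_sd = x$defect_offset_sd %||% 0,
    defect_noise_sd = x$defect_noise_sd %||% 0,
    seed = x$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged two-spot time-lapse fixture configuration
#'
#' An aptamer-functionalized grating next to a non-aptamer control,
#' recorded at 5 frames per minute for 20 minutes with analyte added at
#' 5 minutes, with realistic camera noise, broadband scatter, and a defect
#' pixel population. The aptamer spot's injected steady-state response is a
#' 20 percent green-intensity increase.
#'
#' @param seed Optional seed override.
#' @return A [simulation_config()].
#' @export
fig6_config <- function(seed = NULL) {
  path <- system.file("extdata", "fig6.yaml", package = "braggsense")
  cfg <- read_simulation_config(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
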