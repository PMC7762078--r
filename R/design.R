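#' Maximum useful grating height for a given line width
#'
#' Diffraction efficiency grows linearly with multilayer height only up to
#' about one tenth of the grating line width, so that is the practical
#' height bound for a grating transducer.
#'
#' @param line_width_nm Grating line width, nm.
#' @return Height bound, nm.
#' @export
grating_height_bound <- function(line_width_nm = 300) {
  stopifnot(is.finite(line_width_nm), line_width_nm > 0)
  line_width_nm / 10
}

#' How much thinner a grating is than a thick multilayer spot
#'
#' @param multilayer_nm Thickness of a drop-cast multilayer spot, nm
#'   (default 1 micrometer).
#' @param grating_height_nm Grating height bound, nm.
#' @return Dimensionless thickness ratio.
#' @export
multilayer_thickness_ratio <- function(multilayer_nm = 1000,
                                       grating_height_nm = grating_height_bound()) {
  stopifnot(multilayer_nm > 0, grating_height_nm > 0)
  multilayer_nm / grating_height_nm
}

#' Multiplexing capacity of a camera-addressed sensor array
#'
#' If every camera pixel images a distinct sensor element of the array, the
#' number of simultaneous tests per droplet equals the pixel count.
#'
#' @param megapixels Camera resolution in megapixels.
#' @param sensors_per_pixel Sensors addressed per pixel (1 for one sensor
#'   element per pixel).
#' @return Number of parallel tests.
#' @export
multiplex_capacity <- function(megapixels = 1.4, sensors_per_pixel = 1) {
  stopifnot(megapixels > 0, sensors_per_pixel > 0)
  megapixels * 1e6 * sensors_per_pixel
}
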