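#' Split an RGB frame into channel images
#'
#' Channel order contract: index 1 = red, 2 = green, 3 = blue.
#'
#' @param frame `rows x cols x 3` numeric array.
#' @return Named list with `red`, `green`, `blue` matrices.
#' @export
split_channels <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3) {
    stop("frame must be a rows x cols x 3 RGB array, got dims: ",
         paste(d, collapse = " x "))
  }
  list(red = frame[, , 1], green = frame[, , 2], blue = frame[, , 3])
}

#' Green:red ratio image
#'
#' Bragg-diffraction pixels are green-dominant while broadband scatter is
#' color-neutral, so the elementwise quotient `green / (red + epsilon)`
#' separates the two populations. The stabilizing `epsilon` defaults to one
#' 16-bit intensity quantum so dark pixels cannot blow up the ratio.
#'
#' @param green,red Same-shape single-channel matrices.
#' @param epsilon Non-negative stabilizer added to the denominator. With
#'   `epsilon = 0`, every red pixel must be strictly positive.
#' @return A `ratio_image`: a matrix of ratios with the epsilon used recorded
#'   in `attr(, "epsilon")`.
#' @export
ratio_image <- function(green, red, epsilon = 1 / 65535) {
  stopifnot(identical(dim(green), dim(red)), epsilon >= 0)
  if (epsilon == 0 && any(red == 0)) {
    stop("red channel contains zeros; set epsilon > 0 to stabilize the division")
  }
  r <- green / (red + epsilon)
  structure(r, epsilon = epsilon, class = c("ratio_image", class(r)))
}

#' Threshold a ratio image into a Bragg-pixel mask
#'
#' Inclusive comparison: a pixel is kept when its green:red ratio is at least
#' `tau`, which makes ties deterministic and the masks nested in `tau`.
#'
#' @param ratio A [ratio_image()] (or plain matrix of ratios).
#' @param tau Positive ratio threshold.
#' @return A `pixel_mask`: logical matrix with provenance `"threshold"`.
#' @export
threshold_bragg <- function(ratio, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  pixel_mask(unclass(ratio) >= tau, provenance = "threshold")
}

#' Construct a pixel mask
#'
#' @param mask Logical matrix.
#' @param provenance One of `"threshold"`, `"sd_band"`, `"manual"`.
#' @return Logical matrix of class `pixel_mask`.
#' @export
pixel_mask <- function(mask, provenance = c("manual", "threshold", "sd_band")) {
  provenance <- match.arg(provenance)
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(mask, provenance = provenance,
            class = c("pixel_mask", class(mask)))
}

#' Data-driven ratio threshold (Otsu)
#'
#' The two-class Otsu split of the ratio histogram. On scenes where Bragg and
#' scatter populations are separable, the split lands between the two modes.
#'
#' @param ratio A [ratio_image()] or numeric matrix.
#' @param levels Number of histogram levels for the split.
#' @return A single threshold on the ratio scale.
#' @export
suggest_threshold <- function(ratio, levels = 256) {
  x <- unclass(ratio)
  if (length(x) == 0) stop("empty ratio image")
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("ratio image is constant; choose tau manually")
  }
  EBImage::otsu(x, range = rng, levels = levels)
}
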