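#' Bin masked pixels by fluorescence intensity
#'
#' Equal-width bins spanning the observed fluorescence range of the masked
#' pixels. Fluorescence is the height proxy, so binning by fluorescence is
#' binning by grating height. The last bin is closed on the right, so every
#' masked pixel falls in exactly one bin. Constant fluorescence collapses to
#' a single bin.
#'
#' @param fluor Fluorescence matrix, a.u.
#' @param mask A `pixel_mask` (logical matrix) selecting the pixels to bin.
#' @param n_bins Number of bins (>= 1).
#' @return List with `bin` (integer matrix, `NA` off the mask) and `edges`
#'   (numeric vector of length `n_bins + 1`, or length 2 for the degenerate
#'   constant case).
#' @export
bin_by_fluorescence <- function(fluor, mask, n_bins = 10) {
  stopifnot(identical(dim(fluor), dim(mask)), n_bins >= 1)
  if (!any(mask)) stop("mask is empty; nothing to bin")
  vals <- fluor[mask]
  rng <- range(vals)
  bin <- matrix(NA_integer_, nrow(fluor), ncol(fluor))
  if (diff(rng) == 0) {
    edges <- c(rng[1], rng[2])
    bin[mask] <- 1L
    return(list(bin = bin, edges = edges))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin[mask] <- findInterval(vals, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
  list(bin = bin, edges = edges)
}

#' One-standard-deviation pixel selection within fluorescence bins
#'
#' The pixel-refinement rule: within each fluorescence (height) bin, keep
#' only the pixels whose initial green diffraction intensity lies within
#' `k_sd` sample standard deviations of the bin mean. Pixels far off the
#' linear height-diffraction relation (unstable or defective grating
#' regions, misclassified scatter) are discarded. Bins with fewer than
#' `min_bin_n` pixels are dropped entirely: too few pixels to estimate an SD.
#'
#' @param green0 Initial (pre-addition) green channel image, typically the
#'   mean over the baseline window.
#' @param fluor Co-registered fluorescence image.
#' @param mask Input `pixel_mask` (usually the Bragg threshold mask).
#' @param n_bins Number of fluorescence bins.
#' @param k_sd Band half-width in sample SDs; boundary inclusive.
#' @param min_bin_n Minimum bin occupancy; bins below it are dropped.
#' @param method `"bin_mean"` (default) bands around each bin's mean green
#'   intensity, as the selection rule is stated; `"residual"` bands the
#'   residuals of a single global green-on-fluorescence regression instead,
#'   which retains every pixel of an exactly linear (noise-free) scene.
#' @return List with `mask` (refined `pixel_mask`, always a subset of the
#'   input) and `stats` (data.frame of per-bin count, mean, SD, kept count,
#'   and bin center).
#' @export
sd_band_select <- function(green0, fluor, mask, n_bins = 10, k_sd = 1,
                           min_bin_n = 3,
                           method = c("bin_mean", "residual")) {
  stopifnot(identical(dim(green0), dim(mask)), k_sd >= 0)
  method <- match.arg(method)
  binned <- bin_by_fluorescence(fluor, mask, n_bins)
  bins_present <- sort(unique(binned$bin[mask]))

  resid_img <- NULL
  if (method == "residual") {
    fit <- fit_height_diffraction(green0, fluor, mask)
    resid_img <- green0 - (fit$intercept + fit$slope * fluor)
    s_res <- stats::sd(resid_img[mask])
  }

  keep <- matrix(FALSE, nrow(mask), ncol(mask))
  stats_rows <- lapply(bins_present, function(b) {
    in_bin <- !is.na(binned$bin) & binned$bin == b
    g <- green0[in_bin]
    n <- length(g)
    mu <- mean(g)
    s <- stats::sd(g)  # sample (n - 1) convention
    kept_n <- 0L
    if (n >= min_bin_n) {
      # inclusive boundary; the epsilon keeps the SD = 0 case (identical
      # intensities, or exact residuals) from being broken by float jitter
      eps <- sqrt(.Machine$double.eps) * max(1, abs(mu))
      sel <- if (method == "bin_mean") {
        in_bin & abs(green0 - mu) <= k_sd * s + eps
      } else {
        in_bin & abs(resid_img) <= k_sd * s_res + eps
      }
      keep[sel] <<- TRUE
      kept_n <- sum(sel)
    }
    ne <- length(binned$edges)
    center <- if (ne == 2) mean(binned$edges) else {
      (binned$edges[b] + binned$edges[b + 1]) / 2
    }
    data.frame(bin = b, center = center, n = n, mean_green = mu,
               sd_green = s, kept = kept_n)
  })
  stats <- do.call(rbind, stats_rows)
  if (!any(keep)) {
    stop("all fluorescence bins were dropped (occupancy < ", min_bin_n,
         "); use fewer bins")
  }
  list(mask = pixel_mask(keep, provenance = "sd_band"), stats = stats)
}

#' Fit the height-diffraction relation
#'
#' Ordinary least squares of initial green diffraction intensity on
#' fluorescence intensity over the masked pixels. Because fluorescence is
#' proportional to multilayer height, the slope estimates the ratio of the
#' diffraction gain to the fluorescence gain, and r-squared measures how
#' well the pixels obey the linear height-diffraction relation.
#'
#' @param green0 Initial green channel image.
#' @param fluor Fluorescence image.
#' @param mask `pixel_mask` over which to fit (>= 2 pixels, fluorescence not
#'   constant).
#' @return List of class `height_diffraction_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_pixels`.
#' @export
fit_height_diffraction <- function(green0, fluor, mask) {
  stopifnot(identical(dim(green0), dim(mask)))
  x <- fluor[mask]
  y <- green0[mask]
  if (length(x) < 2) stop("need at least 2 masked pixels to fit")
  if (stats::var(x) == 0) stop("fluorescence is constant over the mask; cannot fit")
  fit <- stats::lm(y ~ x)
  syy <- sum((y - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      # computed directly so an exact fit does not trip summary.lm warnings
      r_squared = if (syy > 0) max(0, min(1, 1 - rss / syy)) else 1,
      n_pixels = length(x)
    ),
    class = "height_diffraction_fit"
  )
}

#' @export
print.height_diffraction_fit <- function(x, ...) {
  cat(sprintf(
    "<height_diffraction_fit> slope = %.4g, intercept = %.4g, r^2 = %.4f, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$n_pixels
  ))
  invisible(x)
}
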