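#' Extract a sensorgram from a stack over a pixel mask
#'
#' The sensorgram is the mean green diffraction intensity over the selected
#' pixels at each frame, with a baseline defined as the mean over the
#' pre-addition window.
#'
#' @param stack An [image_stack()].
#' @param mask Non-empty `pixel_mask`.
#' @param baseline_window Integer frame indices forming the baseline (must be
#'   non-empty; typically [baseline_frames()]).
#' @param label Sample identifier, e.g. `"aptamer"` or `"control"`.
#' @return Object of class `sensorgram`: `t` (minutes), `I` (a.u.),
#'   `I0` (baseline, a.u.), `label`.
#' @export
extract_sensorgram <- function(stack, mask, baseline_window,
                               label = "sample") {
  if (!any(mask)) stop("mask is empty; no pixels to extract")
  if (length(baseline_window) == 0) stop("baseline window is empty")
  stopifnot(all(baseline_window >= 1), all(baseline_window <= n_frames(stack)))
  idx <- which(mask)
  nf <- n_frames(stack)
  I <- vapply(seq_len(nf), function(f) {
    mean(stack$frames[, , 2, f][idx])
  }, numeric(1))
  I0 <- mean(I[baseline_window])
  if (I0 <= 0) stop("baseline intensity must be positive")
  structure(
    list(t = stack$t_min, I = I, I0 = I0, label = label),
    class = "sensorgram"
  )
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf(
    "<sensorgram> '%s': %d frames, t = %.2f..%.2f min, I0 = %.4g a.u.\n",
    x$label, length(x$t), min(x$t), max(x$t), x$I0
  ))
  invisible(x)
}

#' Coerce a sensorgram to a data frame
#' @param x A `sensorgram`.
#' @param ... Unused.
#' @return data.frame with `t_min`, `I`, `pct_change`, `label` columns.
#' @export
as.data.frame.sensorgram <- function(x, ...) {
  data.frame(
    t_min = x$t, I = x$I,
    pct_change = 100 * (x$I - x$I0) / x$I0,
    label = x$label
  )
}

# Index of the recorded frame nearest t_query; earlier frame on ties.
nearest_frame <- function(t, t_query) {
  if (t_query < min(t) || t_query > max(t)) {
    stop(sprintf("t_query = %g min outside recorded range [%g, %g]",
                 t_query, min(t), max(t)))
  }
  which.min(abs(t - t_query))
}

#' Percent change of a sensorgram at a query time
#'
#' `100 * (I(t_nearest) - I0) / I0`, with `t_nearest` the recorded frame time
#' closest to `t_query` (earlier frame on ties). Invariant under uniform
#' rescaling of all intensities.
#'
#' @param s A `sensorgram`.
#' @param t_query Query time, minutes, within the recorded range.
#' @return Percent change (a plain number; 20 means +20 percent).
#' @export
percent_change <- function(s, t_query) {
  f <- nearest_frame(s$t, t_query)
  100 * (s$I[f] - s$I0) / s$I0
}

#' Final/initial green-channel change-ratio image
#'
#' The per-pixel quotient of the green channel at a final frame over an
#' initial frame; 1 means no change, values above 1 show where diffraction
#' increased upon binding.
#'
#' @param stack An [image_stack()].
#' @param frame_final,frame_initial Frame indices.
#' @param epsilon Non-negative stabilizer for the division.
#' @return Single-channel matrix of ratios.
#' @export
change_ratio_image <- function(stack, frame_final, frame_initial,
                               epsilon = 1 / 65535) {
  nf <- n_frames(stack)
  stopifnot(frame_final >= 1, frame_final <= nf,
            frame_initial >= 1, frame_initial <= nf, epsilon >= 0)
  g1 <- stack$frames[, , 2, frame_final]
  g0 <- stack$frames[, , 2, frame_initial]
  g1 / (g0 + epsilon)
}

#' Percent change by fluorescence (height) bin
#'
#' Splits the masked pixels into fluorescence bins and reports each bin's
#' percent change at the query time. With height-scaled response amplitude
#' this reproduces the stronger-response-in-taller-gratings trend.
#'
#' @param stack An [image_stack()].
#' @param fluor Fluorescence image.
#' @param mask `pixel_mask`.
#' @param n_bins Number of fluorescence bins.
#' @param t_query Query time, minutes.
#' @param baseline_window Integer frame indices for the baseline.
#' @param min_bin_n Minimum bin occupancy; smaller bins are omitted.
#' @return data.frame of class `binned_response`: `bin`, `center` (a.u.),
#'   `n`, `pct_change` (percent).
#' @export
height_binned_response <- function(stack, fluor, mask, n_bins, t_query,
                                   baseline_window, min_bin_n = 3) {
  binned <- bin_by_fluorescence(fluor, mask, n_bins)
  bins_present <- sort(unique(binned$bin[mask]))
  rows <- lapply(bins_present, function(b) {
    in_bin <- !is.na(binned$bin) & binned$bin == b
    if (sum(in_bin) < min_bin_n) return(NULL)
    s <- extract_sensorgram(stack, pixel_mask(in_bin), baseline_window,
                            label = sprintf("bin%02d", b))
    ne <- length(binned$edges)
    center <- if (ne == 2) mean(binned$edges) else {
      (binned$edges[b] + binned$edges[b + 1]) / 2
    }
    data.frame(bin = b, center = center, n = sum(in_bin),
               pct_change = percent_change(s, t_query))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no fluorescence bin reaches the minimum occupancy")
  out <- do.call(rbind, rows)
  class(out) <- c("binned_response", class(out))
  out
}

#' Differential response of a test sensorgram over its control
#'
#' @param s_test,s_control `sensorgram` objects with overlapping time ranges.
#' @param t_query Query time, minutes, inside both ranges.
#' @return `percent_change(s_test) - percent_change(s_control)`, percent.
#' @export
compare_to_control <- function(s_test, s_control, t_query) {
  lo <- max(min(s_test$t), min(s_control$t))
  hi <- min(max(s_test$t), max(s_control$t))
  if (lo > hi) stop("sensorgram time ranges do not overlap")
  if (t_query < lo || t_query > hi) {
    stop(sprintf("t_query = %g min outside the shared range [%g, %g]",
                 t_query, lo, hi))
  }
  percent_change(s_test, t_query) - percent_change(s_control, t_query)
}
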