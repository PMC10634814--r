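#' Extract peri-event waveform windows
#'
#' Cuts raw-LFP windows around each event peak into an events x time
#' matrix. Events whose window crosses a signal edge are dropped with a
#' warning.
#'
#' @param x Numeric signal (raw LFP of the detection channel).
#' @param peaks Integer peak samples (1-based).
#' @param window_ms `c(lo, hi)` window in ms relative to the peak.
#' @param fs Sampling rate (Hz).
#' @return Numeric matrix (events x samples) with attributes `t_ms` (column
#'   time base), `fs`, `peak_sample` (kept peaks) and `kept` (logical mask
#'   over the input peaks).
#' @export
extract_waveforms <- function(x, peaks, window_ms = c(-200, 200), fs = 1000) {
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2]) {
    stop_("`window_ms` must be c(lo, hi) with lo < hi")
  }
  offs <- ms_to_samples_(window_ms[1], fs):ms_to_samples_(window_ms[2], fs)
  keep <- peaks + offs[1] >= 1 & peaks + tail(offs, 1) <= length(x)
  if (any(!keep)) {
    warn_(sum(!keep), " event(s) too close to a signal edge dropped")
  }
  kept_peaks <- peaks[keep]
  m <- t(vapply(kept_peaks, function(p) x[p + offs], numeric(length(offs))))
  if (length(kept_peaks) == 0) m <- matrix(numeric(0), ncol = length(offs))
  attr(m, "t_ms") <- offs * 1000 / fs
  attr(m, "fs") <- fs
  attr(m, "peak_sample") <- kept_peaks
  attr(m, "kept") <- keep
  m
}

new_mean_waveform_ <- function(t_ms, amplitude, n_events, fs) {
  structure(list(t_ms = t_ms, amplitude = amplitude,
                 n_events = n_events, fs = fs),
            class = "mean_waveform")
}

#' @export
print.mean_waveform <- function(x, ...) {
  cat(sprintf("<mean_waveform> %d samples over [%g, %g] ms @ %g Hz (n = %d events)\n",
              length(x$t_ms), min(x$t_ms), max(x$t_ms), x$fs, x$n_events))
  invisible(x)
}

#' Mean waveform across events
#'
#' Width and amplitude metrics are computed on the average DS waveform, not
#' on single trials, because individual waveforms can carry the dynamics of
#' other overlapping events.
#'
#' @param waveform_matrix An events x time matrix from
#'   [extract_waveforms()], or any numeric matrix with a `t_ms` attribute.
#' @param fs Sampling rate; taken from the matrix attribute when present.
#' @return A `mean_waveform` object (time base in ms relative to the peak,
#'   amplitudes in mV).
#' @export
mean_waveform <- function(waveform_matrix, fs = NULL) {
  if (nrow(waveform_matrix) == 0) stop_("empty waveform matrix")
  t_ms <- attr(waveform_matrix, "t_ms")
  if (is.null(t_ms)) stop_("waveform matrix lacks a `t_ms` attribute")
  fs <- fs %||% attr(waveform_matrix, "fs") %||% 1000
  new_mean_waveform_(t_ms, colMeans(waveform_matrix),
                     nrow(waveform_matrix), fs)
}

#' Z-score a mean waveform
#'
#' The scaled mean waveform (z-score over the -200..200 ms window) removes
#' the laminar amplitude gradient so waveform shape can be compared across
#' channels and animals; the scaled peak amplitude is its value at t = 0.
#'
#' @param mw A `mean_waveform`.
#' @return A `mean_waveform` with mean 0 and sample sd 1 over its window.
#' @export
scaled_waveform <- function(mw) {
  stopifnot(inherits(mw, "mean_waveform"))
  s <- sd(mw$amplitude)
  if (!is.finite(s) || s == 0) stop_("constant waveform cannot be z-scored")
  new_mean_waveform_(mw$t_ms, (mw$amplitude - mean(mw$amplitude)) / s,
                     mw$n_events, mw$fs)
}

#' Cubic-spline resampling of a mean waveform
#'
#' The 1-ms sampling period at 1 kHz quantizes width estimates; cubic
#' spline interpolation onto a finer grid (default 4 kHz, 0.25 ms) reduces
#' this granularity. Original samples are reproduced exactly.
#'
#' @param mw A `mean_waveform`.
#' @param target_fs Target rate in Hz.
#' @return The resampled `mean_waveform`.
#' @export
resample_spline <- function(mw, target_fs = 4000) {
  stopifnot(inherits(mw, "mean_waveform"))
  if (length(mw$t_ms) < 4) stop_("need at least 4 samples for a cubic spline")
  xout <- seq(min(mw$t_ms), max(mw$t_ms), by = 1000 / target_fs)
  fit <- spline(mw$t_ms, mw$amplitude, xout = xout, method = "fmm")
  new_mean_waveform_(fit$x, fit$y, mw$n_events, target_fs)
}

#' Second derivative of a mean waveform
#'
#' Central second differences scaled by the squared sampling period; the
#' two edge samples are dropped. Units are mV/ms^2. The positive lobes of
#' the second derivative mark the upward concavities flanking the peak that
#' define the width limits.
#'
#' @param mw A `mean_waveform`.
#' @return A `mean_waveform`-shaped object holding the second derivative.
#' @export
second_derivative <- function(mw) {
  stopifnot(inherits(mw, "mean_waveform"))
  a <- mw$amplitude
  n <- length(a)
  if (n < 3) stop_("need at least 3 samples for a second derivative")
  dt <- 1000 / mw$fs
  d2 <- (a[3:n] - 2 * a[2:(n - 1)] + a[1:(n - 2)]) / dt^2
  new_mean_waveform_(mw$t_ms[2:(n - 1)], d2, mw$n_events, mw$fs)
}

#' Width of a mean DS waveform from second-derivative concavities
#'
#' The waveform is spline-resampled (default 4 kHz), its second derivative
#' taken, and the width limits placed at the local maxima of the second
#' derivative in the bands -15..-5 ms (start) and 5..15 ms (end); the width
#' is their distance. Because the limits are second-derivative argmaxima,
#' the measurement is invariant to gain and offset: attenuation along the
#' probe changes the waveform amplitude but not its measured width. The
#' half-height width is computed on the same resampled waveform. Ties go to
#' the earliest time; an argmax sitting exactly on a band boundary is
#' flagged `low_confidence`.
#'
#' @param mw A `mean_waveform` covering at least -15..15 ms (for the
#'   half-height metric and its baseline, -200..200 ms is expected).
#' @param start_band,end_band Search bands (ms) for the width limits.
#' @param resample_to Grid for the measurement (Hz).
#' @return A one-row tibble: `width_ms`, `start_ms`, `end_ms`,
#'   `half_height_ms`, `low_confidence`, `resampled_fs`.
#' @examples
#' t <- seq(-200, 200)
#' g <- exp(-t^2 / (2 * 16))  # Gaussian, sigma = 4 ms
#' mw <- structure(list(t_ms = t, amplitude = g, n_events = 1L, fs = 1000),
#'                 class = "mean_waveform")
#' measure_width(mw)  # width ~ 2 * 4 * sqrt(3), half height ~ 9.42 ms
#' @export
measure_width <- function(mw, start_band = c(-15, -5), end_band = c(5, 15),
                          resample_to = 4000) {
  stopifnot(inherits(mw, "mean_waveform"))
  if (min(mw$t_ms) > start_band[1] || max(mw$t_ms) < end_band[2]) {
    stop_("waveform does not cover the width search bands")
  }
  rs <- resample_spline(mw, resample_to)
  d2 <- second_derivative(rs)
  band_argmax <- function(band) {
    in_band <- d2$t_ms >= band[1] & d2$t_ms <= band[2]
    tt <- d2$t_ms[in_band]
    vv <- d2$amplitude[in_band]
    i <- which.max(vv)  # earliest tie
    list(t = tt[i], boundary = i == 1L || i == length(vv))
  }
  start <- band_argmax(start_band)
  end <- band_argmax(end_band)
  hh <- tryCatch(half_height_width(rs), error = function(e) NA_real_)
  tibble(
    width_ms = end$t - start$t,
    start_ms = start$t,
    end_ms = end$t,
    half_height_ms = hh,
    low_confidence = start$boundary || end$boundary,
    resampled_fs = resample_to
  )
}

#' Width at half height
#'
#' Distance between the first crossings of half the peak height on either
#' side of t = 0, with sub-grid linear interpolation at the crossings. The
#' baseline is the waveform mean over -200..-100 ms (an event-free segment
#' by the spacing rule); when that range is absent the earliest tenth of
#' the window is used.
#'
#' @param mw A `mean_waveform` with a positive peak at t = 0.
#' @param max_lag_ms Crossings must occur within this distance of the peak.
#' @return Half-height width in ms.
#' @export
half_height_width <- function(mw, max_lag_ms = 50) {
  stopifnot(inherits(mw, "mean_waveform"))
  t <- mw$t_ms; a <- mw$amplitude
  base_idx <- t >= -200 & t <= -100
  if (!any(base_idx)) base_idx <- seq_along(t) <= max(1, length(t) %/% 10)
  baseline <- mean(a[base_idx])
  peak_i <- which.min(abs(t))
  height <- a[peak_i] - baseline
  if (height <= 0) stop_("peak not above baseline; half height undefined")
  half <- baseline + height / 2
  cross <- function(side) {
    idx <- if (side < 0) seq(peak_i - 1, 1) else seq(peak_i + 1, length(t))
    below <- idx[which(a[idx] < half)[1]]
    if (is.na(below) || abs(t[below]) > max_lag_ms) {
      stop_("no half-height crossing within ", max_lag_ms, " ms of the peak")
    }
    inner <- below - side  # neighbour toward the peak (still above half)
    t[below] + (t[inner] - t[below]) *
      (half - a[below]) / (a[inner] - a[below])
  }
  cross(+1) - cross(-1)
}

#' Coefficient of variation
#'
#' Ratio of the standard deviation to the mean (sample sd, n - 1
#' denominator), used to contrast the spread of DS metrics across channels
#' and animals.
#'
#' @param values Numeric vector with nonzero mean.
#' @return sd / mean.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop_("coefficient of variation undefined for zero mean")
  sd(values) / m
}
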