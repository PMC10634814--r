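#' Plot a mean waveform
#'
#' @param object A `mean_waveform`.
#' @param ... Unused.
#' @return A ggplot of amplitude against time relative to the peak.
#' @export
autoplot.mean_waveform <- function(object, ...) {
  df <- tibble(t_ms = object$t_ms, amplitude = object$amplitude)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from peak (ms)", y = "amplitude (mV)",
                  title = sprintf("mean waveform (n = %d events)",
                                  object$n_events))
}

#' Plot the delta-state series
#'
#' Relative delta power per one-minute window with the strong-delta
#' threshold; strong windows highlighted.
#'
#' @param object A `delta_states` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_states <- function(object, ...) {
  df <- as_tibble(unclass_tbl_(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_start_s / 60,
                                   y = .data$relative_delta_power)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$strong)) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = "relative delta power",
                  colour = "strong delta")
}

#' Plot per-type mean waveforms of a classification
#'
#' @param object A `ds_classification`.
#' @param x Signal (numeric vector at 1 kHz) or [lfp_recording()] the
#'   events were classified on.
#' @param channel Channel for multichannel recordings.
#' @param window_ms Waveform window.
#' @param ... Unused.
#' @return A ggplot with one mean waveform per DS type.
#' @export
plot_type_waveforms <- function(object, x, channel = NULL,
                                window_ms = c(-200, 200), ...) {
  if (inherits(x, "lfp_recording")) {
    fs <- x$fs
    x <- channel_signal_(x, channel %||% 1)
  } else {
    fs <- 1000
  }
  typed <- object[!object$excluded & !is.na(object$label), ]
  df <- purrr::map_dfr(sort(unique(typed$label)), function(k) {
    W <- extract_waveforms(x, typed$peak_sample[typed$label == k],
                           window_ms = window_ms, fs = fs)
    mw <- mean_waveform(W)
    tibble(type = paste0("DS", k), t_ms = mw$t_ms,
           amplitude = mw$amplitude)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$amplitude,
                                   colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from peak (ms)", y = "amplitude (mV)",
                  colour = NULL)
}
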