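# Welch power spectral density: averaged periodograms of Hann-windowed
# overlapping segments. Only power ratios are used downstream, so scaling
# constants are irrelevant.
welch_psd_ <- function(x, fs, segment_s = 8, overlap = 0.5) {
  n <- length(x)
  seg <- min(n, round(segment_s * fs))
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  acc <- numeric(floor(seg / 2))
  for (s in starts) {
    v <- x[s:(s + seg - 1)] * w
    p <- Mod(fft(v))^2
    acc <- acc + p[2:(floor(seg / 2) + 1)]
  }
  list(freq = seq_len(floor(seg / 2)) * fs / seg, power = acc / length(starts))
}

#' Relative delta power per one-minute window
#'
#' For each full non-overlapping window, computes the fraction of the
#' IMF's Welch spectral power that lies in the delta band (0-5 Hz) relative
#' to its full-band power. Windows where the fraction strictly exceeds 0.9
#' are labeled strong delta; a fraction of exactly 0.9 is weak.
#'
#' @param imf Numeric vector: the delta-dominant IMF.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default one minute); a partial
#'   trailing window is discarded.
#' @param delta_band Delta band in Hz.
#' @param threshold Strong-delta threshold on the relative power (strict
#'   inequality).
#' @return A `delta_states` tibble with `window_start_s`,
#'   `relative_delta_power` (in `[0, 1]`) and `strong`; attributes `fs`,
#'   `window_s`.
#' @export
relative_delta_power <- function(imf, fs, window_s = 60,
                                 delta_band = c(0, 5), threshold = 0.9) {
  win_n <- round(window_s * fs)
  if (win_n < 2 || length(imf) < win_n) {
    stop_("IMF shorter than one analysis window")
  }
  n_win <- floor(length(imf) / win_n)
  ratio <- vapply(seq_len(n_win), function(i) {
    seg <- imf[((i - 1) * win_n + 1):(i * win_n)]
    psd <- welch_psd_(seg, fs)
    total <- sum(psd$power)
    if (total == 0) return(0)
    sum(psd$power[psd$freq > delta_band[1] & psd$freq <= delta_band[2]]) /
      total
  }, numeric(1))
  out <- tibble(
    window_start_s = (seq_len(n_win) - 1) * window_s,
    relative_delta_power = ratio,
    strong = ratio > threshold
  )
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  class(out) <- c("delta_states", class(out))
  out
}

#' Segment a recording into strong and weak delta
#'
#' Convenience orchestrator: EMD of the raw LFP, selection of the
#' delta-dominant IMF, then per-window relative delta power. Dentate spikes
#' occur almost exclusively during periods of increased delta power
#' (quiet rest / slow-wave sleep), so DS rates are reported over strong
#' windows only.
#'
#' @param x A numeric signal or an [lfp_recording()].
#' @param channel Channel index or id when `x` is a multichannel recording.
#' @param fs Sampling rate; inferred from the recording when omitted.
#' @param imf_index Default IMF index (see [select_delta_imf()]).
#' @param auto Auto-select the delta IMF by band dominance.
#' @param window_s,threshold Passed to [relative_delta_power()].
#' @return A `delta_states` tibble (see [relative_delta_power()]) with an
#'   `imf_index` attribute.
#' @export
delta_states <- function(x, channel = NULL, fs = NULL, imf_index = 5,
                         auto = FALSE, window_s = 60, threshold = 0.9) {
  if (inherits(x, "lfp_recording")) {
    if (is.null(channel) && n_channels_(x) > 1) {
      stop_("`channel` required for multichannel recordings")
    }
    fs <- x$fs
    x <- channel_signal_(x, channel %||% 1)
  }
  if (is.null(fs)) stop_("`fs` required when `x` is a plain vector")
  dec <- emd_decompose(x, fs)
  idx <- select_delta_imf(dec, index = imf_index, auto = auto)
  out <- relative_delta_power(dec$imfs[, idx], fs, window_s = window_s,
                              threshold = threshold)
  attr(out, "imf_index") <- idx
  out
}

#' Mean DS rate during strong delta
#'
#' Average, over the strong-delta one-minute windows, of the number of
#' detected events falling in each window, expressed in events per minute.
#'
#' @param catalog Event catalog tibble with `peak_sample` (1-based, at the
#'   rate in `fs`).
#' @param states A `delta_states` tibble from [relative_delta_power()] /
#'   [delta_states()] for the same recording.
#' @param fs Sampling rate of the catalog's peak samples.
#' @return Events per minute (numeric scalar). `NA` with a warning when no
#'   window is labeled strong.
#' @export
ds_rate_strong_delta <- function(catalog, states, fs = 1000) {
  window_s <- attr(states, "window_s") %||% 60
  strong <- states[states$strong, , drop = FALSE]
  if (nrow(strong) == 0) {
    warn_("no strong-delta windows; DS rate undefined")
    return(NA_real_)
  }
  t_s <- (catalog$peak_sample - 1) / fs
  counts <- vapply(strong$window_start_s, function(s0) {
    sum(t_s >= s0 & t_s < s0 + window_s)
  }, numeric(1))
  mean(counts) * 60 / window_s
}
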