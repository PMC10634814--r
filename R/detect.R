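#' Detection parameters
#'
#' Defaults follow the standard DS detection recipe: 1-200 Hz fourth-order
#' Butterworth filtering, a threshold of seven times the median absolute
#' amplitude of the filtered trace, a minimum inter-peak spacing of 50 ms,
#' a 20-ms peak offset-correction window on the raw LFP, and Tukey-fence
#' amplitude outlier removal.
#'
#' @param band Passband in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled while phase is zero).
#' @param threshold_multiplier Threshold as a multiple of the median
#'   absolute amplitude of the filtered signal.
#' @param min_spacing_ms Minimum distance between detected peaks.
#' @param offset_window_ms Total width of the raw-LFP window searched for
#'   the true peak around each filtered-LFP peak.
#' @param use_reference_subtraction Subtract a reference channel before
#'   filtering (artifact mitigation; requires `reference_channel`).
#' @param use_tukey_filter Drop events whose raw peak amplitude falls
#'   outside the Tukey fences of the amplitude distribution.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(band = c(1, 200), filter_order = 4,
                             threshold_multiplier = 7, min_spacing_ms = 50,
                             offset_window_ms = 20,
                             use_reference_subtraction = TRUE,
                             use_tukey_filter = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            filter_order > 0, threshold_multiplier > 0,
            min_spacing_ms > 0, offset_window_ms > 0)
  structure(list(band = band, filter_order = filter_order,
                 threshold_multiplier = threshold_multiplier,
                 min_spacing_ms = min_spacing_ms,
                 offset_window_ms = offset_window_ms,
                 use_reference_subtraction = use_reference_subtraction,
                 use_tukey_filter = use_tukey_filter),
            class = "detection_params")
}

#' Subtract a reference signal from the target LFP
#'
#' Removes deflections common to the whole probe (movement and electrical
#' artifacts affect all recording sites with the same waveform, so the
#' difference cancels them exactly).
#'
#' @param target,reference Equal-length numeric vectors.
#' @return The elementwise difference `target - reference`.
#' @export
subtract_reference <- function(target, reference) {
  if (length(target) != length(reference)) {
    stop_("target and reference signals differ in length (",
          length(target), " vs ", length(reference), ")")
  }
  target - reference
}

#' Zero-phase Butterworth bandpass filter
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz); must exceed twice the upper band edge.
#' @param band Passband in Hz.
#' @param order Butterworth order.
#' @return Filtered signal of the same length (forward-backward filtering,
#'   zero phase distortion).
#' @export
bandpass_filter <- function(x, fs, band = c(1, 200), order = 4) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    stop_("invalid band: must be c(low, high) with 0 < low < high")
  }
  if (fs <= 2 * band[2]) stop_("fs must exceed twice the upper band edge")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Find threshold-crossing peaks with minimum spacing
#'
#' Local maxima of the filtered signal above
#' `threshold_multiplier * median(|signal|)` are candidate DS peaks. When
#' two candidates are closer than `min_spacing_ms`, the smaller peaks are
#' eliminated first until the spacing condition holds.
#'
#' @param x Filtered signal.
#' @param fs Sampling rate (Hz).
#' @param params A [detection_params()].
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
detect_peaks <- function(x, fs, params = detection_params()) {
  if (length(x) == 0) stop_("empty signal")
  threshold <- params$threshold_multiplier * median(abs(x))
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- x[2:(n - 1)]
  is_peak <- core > x[1:(n - 2)] & core >= x[3:n] & core > threshold
  candidates <- which(is_peak) + 1L
  enforce_spacing_(candidates, x[candidates],
                   ms_to_samples_(params$min_spacing_ms, fs))
}

# Repeatedly delete the smallest-amplitude peak involved in a spacing
# violation until all pairwise distances are >= min_gap samples.
enforce_spacing_ <- function(peaks, amplitudes, min_gap) {
  if (length(peaks) < 2) return(peaks)
  ord <- order(peaks)
  peaks <- peaks[ord]; amplitudes <- amplitudes[ord]
  repeat {
    gaps <- diff(peaks)
    bad <- which(gaps < min_gap)
    if (length(bad) == 0) return(peaks)
    involved <- unique(c(bad, bad + 1L))
    drop <- involved[which.min(amplitudes[involved])]
    peaks <- peaks[-drop]; amplitudes <- amplitudes[-drop]
    if (length(peaks) < 2) return(peaks)
  }
}

#' Correct peak positions on the raw LFP
#'
#' Filtering deforms the waveform, so each peak detected on the filtered
#' trace is moved to the maximum of the raw LFP within a window (default
#' 20 ms total) centred on it. Ties go to the earliest sample. Peaks whose
#' window crosses a signal edge are dropped with a warning.
#'
#' @param raw Raw (unfiltered) signal of the target channel.
#' @param peaks Integer peak samples from [detect_peaks()].
#' @param fs Sampling rate (Hz).
#' @param offset_window_ms Total window width in ms.
#' @return A tibble with `peak_sample` (corrected) and `offset_ms`
#'   (correction applied, in ms).
#' @export
correct_peak_offsets <- function(raw, peaks, fs = 1000,
                                 offset_window_ms = 20) {
  half <- ms_to_samples_(offset_window_ms / 2, fs)
  ok <- peaks - half >= 1 & peaks + half <= length(raw)
  if (any(!ok)) {
    warn_(sum(!ok), " peak(s) within ", offset_window_ms / 2,
          " ms of a signal edge dropped")
  }
  peaks <- peaks[ok]
  corrected <- vapply(peaks, function(p) {
    win <- raw[(p - half):(p + half)]
    p - half - 1L + which.max(win)   # which.max returns the earliest tie
  }, integer(1))
  tibble(peak_sample = corrected,
         offset_ms = (corrected - peaks) * 1000 / fs)
}

#' Flag amplitude outliers by Tukey's fences
#'
#' Events whose peak amplitude falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear interpolation) are
#' treated as residual artifacts. The interval is closed: values exactly at
#' a fence are kept. With fewer than 4 events the filter is a no-op.
#'
#' @param amplitudes Numeric vector of peak amplitudes.
#' @return Logical keep mask of the same length.
#' @export
remove_amplitude_outliers <- function(amplitudes) {
  if (length(amplitudes) < 4) {
    if (length(amplitudes) > 0) {
      warn_("fewer than 4 events; Tukey outlier filter skipped")
    }
    return(rep(TRUE, length(amplitudes)))
  }
  q <- quantile(amplitudes, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  amplitudes >= q[1] - 1.5 * iqr & amplitudes <= q[2] + 1.5 * iqr
}

#' Detect dentate spikes in a recording
#'
#' Full detection pipeline on one target channel:
#' optional reference subtraction -> zero-phase bandpass -> threshold peak
#' detection with spacing enforcement -> peak offset correction on the raw
#' target LFP -> optional Tukey amplitude-outlier removal. Events closer
#' than 200 ms to a signal edge are dropped so every downstream waveform
#' window (+/- 200 ms) is fully sampled, and spacing is re-enforced after
#' offset correction.
#'
#' @param recording An [lfp_recording()] at 1 kHz.
#' @param target_channel Channel index or id to detect on (typically the
#'   hilus, where DSs are largest).
#' @param reference_channel Optional channel index or id subtracted before
#'   filtering (used only when `params$use_reference_subtraction` is TRUE).
#' @param params A [detection_params()].
#' @return An event catalog: tibble with `peak_sample`, `amplitude_mv`
#'   (raw-LFP value at the corrected peak), `offset_ms` and `channel`, with
#'   attributes `fs`, `threshold_mv`, `offset_corrected`, `outlier_removed`
#'   and `n_outliers_removed`.
#' @examples
#' out <- synthesize_recording(synth_config(duration_s = 120, n_events = c(20, 20)))
#' detect_dentate_spikes(out$recording, out$target_channel, out$reference_channel)
#' @export
detect_dentate_spikes <- function(recording, target_channel,
                                  reference_channel = NULL,
                                  params = detection_params()) {
  assert_lfp_(recording)
  if (recording$fs != 1000) {
    stop_("detection expects the canonical 1 kHz rate; see decimate_to_1khz()")
  }
  raw <- channel_signal_(recording, target_channel)
  work <- raw
  if (params$use_reference_subtraction && !is.null(reference_channel)) {
    work <- subtract_reference(work,
                               channel_signal_(recording, reference_channel))
  }
  filtered <- bandpass_filter(work, recording$fs, params$band,
                              params$filter_order)
  threshold <- params$threshold_multiplier * median(abs(filtered))
  peaks <- detect_peaks(filtered, recording$fs, params)
  corrected <- correct_peak_offsets(raw, peaks, recording$fs,
                                    params$offset_window_ms)
  # offset correction can merge or crowd peaks; de-duplicate and re-enforce
  keep <- !duplicated(corrected$peak_sample)
  corrected <- corrected[keep, ]
  kept_peaks <- enforce_spacing_(corrected$peak_sample,
                                 raw[corrected$peak_sample],
                                 ms_to_samples_(params$min_spacing_ms,
                                                recording$fs))
  corrected <- corrected[match(kept_peaks, corrected$peak_sample), ]
  # downstream windows are +/- 200 ms; drop events that cannot supply them
  margin <- ms_to_samples_(200, recording$fs)
  in_range <- corrected$peak_sample > margin &
    corrected$peak_sample <= n_samples_(recording) - margin
  corrected <- corrected[in_range, ]
  amplitudes <- raw[corrected$peak_sample]
  n_outliers <- 0L
  if (params$use_tukey_filter) {
    mask <- remove_amplitude_outliers(amplitudes)
    n_outliers <- sum(!mask)
    corrected <- corrected[mask, ]
    amplitudes <- amplitudes[mask]
  }
  catalog <- tibble(
    peak_sample = as.integer(corrected$peak_sample),
    amplitude_mv = amplitudes,
    offset_ms = corrected$offset_ms,
    channel = recording$channel_ids[resolve_channel_(recording,
                                                     target_channel)]
  )
  attr(catalog, "fs") <- recording$fs
  attr(catalog, "threshold_mv") <- threshold
  attr(catalog, "offset_corrected") <- TRUE
  attr(catalog, "outlier_removed") <- params$use_tukey_filter
  attr(catalog, "n_outliers_removed") <- n_outliers
  catalog
}
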