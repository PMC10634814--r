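#' Multichannel LFP recording container
#'
#' A light container for depth-ordered local field potential traces. Samples
#' are stored as a channels x time numeric matrix in millivolts, with channel
#' row 1 the most superficial electrode. The canonical sampling rate for all
#' downstream analyses is 1 kHz (1 sample = 1 ms); higher-rate recordings
#' should be passed through [decimate_to_1khz()] first.
#'
#' @param samples Numeric matrix, channels x time, or a numeric vector for a
#'   single-channel recording.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_ids Character vector of unique channel identifiers ordered
#'   from most superficial (first) to deepest (last). Defaults to
#'   `"ch1"..."chN"`.
#' @param units Unit tag for the sample values; only `"mV"` is used
#'   internally.
#'
#' @return An object of class `lfp_recording`: a list with elements
#'   `samples`, `fs`, `channel_ids`, `units`.
#' @examples
#' rec <- lfp_recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' rec
#' @export
lfp_recording <- function(samples, fs, channel_ids = NULL, units = "mV") {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_("`samples` must be a numeric matrix (channels x time) or vector")
  }
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop_("`fs` must be a single positive number (Hz)")
  }
  if (is.null(channel_ids)) {
    channel_ids <- paste0("ch", seq_len(nrow(samples)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(samples)) {
    stop_("`channel_ids` length (", length(channel_ids),
          ") does not match the number of channels (", nrow(samples), ")")
  }
  if (anyDuplicated(channel_ids)) stop_("`channel_ids` must be unique")
  structure(
    list(samples = unname(samples), fs = as.numeric(fs),
         channel_ids = channel_ids, units = units),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), units %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$units))
  invisible(x)
}

n_channels_ <- function(recording) nrow(recording$samples)
n_samples_ <- function(recording) ncol(recording$samples)

# Resolve a channel given as index or id to a row index.
resolve_channel_ <- function(recording, channel) {
  if (is.character(channel)) {
    idx <- match(channel, recording$channel_ids)
    if (is.na(idx)) stop_("unknown channel id: ", channel)
    return(idx)
  }
  idx <- as.integer(channel)
  if (is.na(idx) || idx < 1 || idx > n_channels_(recording)) {
    stop_("channel index out of range: ", channel)
  }
  idx
}

# Extract one channel as a numeric vector.
channel_signal_ <- function(recording, channel) {
  recording$samples[resolve_channel_(recording, channel), ]
}

assert_lfp_ <- function(recording) {
  if (!inherits(recording, "lfp_recording")) {
    stop_("expected an `lfp_recording` object; see lfp_recording()")
  }
  invisible(recording)
}
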