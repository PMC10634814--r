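#' Write / read an LFP recording as a flat array plus JSON sidecar
#'
#' The on-disk format is a flat little-endian float64 array (channel index
#' varying fastest, i.e. one depth profile per time sample) next to a JSON
#' sidecar `<path>.json` holding `fs`, `channel_ids`, `units` and the array
#' shape. `read_lfp(write_lfp(x, p))` is the identity on samples, sampling
#' rate and channel ids.
#'
#' @param recording An [lfp_recording()].
#' @param path File path for the array; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `write_lfp()` returns `path` invisibly; `read_lfp()` returns an
#'   [lfp_recording()].
#' @export
write_lfp <- function(recording, path) {
  assert_lfp_(recording)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$samples), con, size = 8, endian = "little")
  sidecar <- list(
    fs = recording$fs,
    channel_ids = recording$channel_ids,
    units = recording$units,
    n_channels = n_channels_(recording),
    n_samples = n_samples_(recording),
    order = "channel-fastest",
    dtype = "float64-le"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop_("missing sidecar file: ", sidecar_path)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("fs", "channel_ids", "n_channels", "n_samples")
  missing <- setdiff(required, names(meta))
  if (length(missing)) stop_("sidecar lacks fields: ",
                             paste(missing, collapse = ", "))
  if (!is.numeric(meta$fs) || meta$fs <= 0) stop_("sidecar fs must be > 0")
  n_values <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  values <- readBin(con, what = "double", n = n_values + 1, size = 8,
                    endian = "little")
  if (length(values) != n_values) {
    stop_("array length (", length(values), ") does not match sidecar shape (",
          meta$n_channels, " x ", meta$n_samples, ")")
  }
  lfp_recording(matrix(values, nrow = meta$n_channels), fs = meta$fs,
                channel_ids = meta$channel_ids,
                units = meta$units %||% "mV")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a recording to the canonical 1 kHz rate
#'
#' All detection windows and waveform metrics in this package are specified
#' in milliseconds on a 1 kHz grid, so recordings acquired at higher rates
#' are anti-alias filtered and decimated first. Integer rate ratios use an
#' IIR (Chebyshev) decimator; non-integer ratios fall back to rational
#' polyphase resampling.
#'
#' @param recording An [lfp_recording()] with `fs >= 1000`.
#' @return An [lfp_recording()] with `fs = 1000`. A recording already at
#'   1 kHz is returned unchanged.
#' @export
decimate_to_1khz <- function(recording) {
  assert_lfp_(recording)
  fs <- recording$fs
  if (fs < 1000) stop_("cannot decimate: fs = ", fs, " Hz is below 1 kHz")
  if (fs == 1000) return(recording)
  if (fs %% 1000 == 0) {
    q <- fs / 1000
    out <- t(apply(recording$samples, 1, function(x) {
      # linear-phase FIR decimator: flat passband, no phase distortion
      signal::decimate(x, q, ftype = "fir")
    }))
  } else {
    # rational factor p/q = 1000/fs in lowest terms
    g <- gcd_(1000, fs)
    p <- 1000 / g
    q <- fs / g
    out <- t(apply(recording$samples, 1, function(x) {
      signal::resample(x, p, q)
    }))
  }
  lfp_recording(out, fs = 1000, channel_ids = recording$channel_ids,
                units = recording$units)
}

gcd_ <- function(a, b) if (b == 0) a else gcd_(b, a %% b)

#' Write / read a detected-event catalog as CSV
#'
#' Catalogs are tibbles with columns `peak_sample` (1-based sample index at
#' 1 kHz), `amplitude_mv` (raw-LFP value at the corrected peak) and
#' `channel` (source channel id), as produced by [detect_dentate_spikes()].
#' `read_events()` validates that peak samples are strictly increasing.
#'
#' @param catalog A tibble with at least a `peak_sample` column.
#' @param path CSV file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   catalog tibble.
#' @export
write_events <- function(catalog, path) {
  if (!"peak_sample" %in% names(catalog)) {
    stop_("catalog must have a `peak_sample` column")
  }
  validate_peaks_(catalog$peak_sample)
  write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"peak_sample" %in% names(df)) {
    stop_("events file lacks a `peak_sample` column: ", path)
  }
  validate_peaks_(df$peak_sample)
  as_tibble(df)
}

validate_peaks_ <- function(peaks) {
  if (length(peaks) == 0) return(invisible(TRUE))
  if (anyNA(peaks)) stop_("peak_sample contains missing values")
  if (anyDuplicated(peaks)) stop_("duplicate peak_sample values")
  if (is.unsorted(peaks, strictly = TRUE)) {
    stop_("peak_sample values must be strictly increasing")
  }
  invisible(TRUE)
}
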