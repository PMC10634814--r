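# Shared fixtures, built lazily and cached for the session so the heavier
# synthetic recordings are generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture_ <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a mean_waveform from explicit samples (bypassing event averaging)
mw_ <- function(t_ms, amplitude, fs = 1000) {
  structure(list(t_ms = t_ms, amplitude = amplitude, n_events = 1L, fs = fs),
            class = "mean_waveform")
}

gaussian_mw_ <- function(sigma_ms = 4, span = 200, fs = 1000) {
  t <- seq(-span, span, by = 1000 / fs)
  mw_(t, exp(-t^2 / (2 * sigma_ms^2)), fs)
}

# 5-minute, 8-channel two-type recording used by several module tests
small_two_type_ <- function() {
  fixture_("small_two_type", function() {
    out <- synthesize_recording(
      synth_config(duration_s = 300, n_events = c(80, 80), seed = 42)
    )
    out$catalog <- detect_dentate_spikes(out$recording, out$target_channel,
                                         out$reference_channel)
    mi <- vapply(out$catalog$peak_sample, function(p) {
      which.min(abs(out$truth$peak_sample - p))
    }, integer(1))
    hit <- abs(out$truth$peak_sample[mi] - out$catalog$peak_sample) <= 2
    out$catalog_true_type <- ifelse(hit, out$truth$type[mi], NA_integer_)
    out
  })
}

# events x time waveform matrix built directly from templates + white
# noise, aligned at the template peak (no detection involved)
template_matrix_ <- function(n1, n2, noise_sd = 0.1, seed = 1,
                             amp_mean = 1.5, amp_sd = 0.25,
                             window_ms = c(-200, 200), n_artifacts = 0,
                             artifact_amp = 7.5) {
  set.seed(seed)
  t_ms <- window_ms[1]:window_ms[2]
  tpl1 <- make_ds_template(1, 22, -0.12, span_ms = window_ms)$shape
  tpl2 <- make_ds_template(2, 14, -0.3, span_ms = window_ms)$shape
  n <- n1 + n2
  types <- sample(rep.int(c(1L, 2L), c(n1, n2)))
  amps <- stats::rlnorm(n, log(amp_mean) - 0.5 * log(1 + (amp_sd / amp_mean)^2),
                        sqrt(log(1 + (amp_sd / amp_mean)^2)))
  # noise rows cut from one long pink (band-limited) series, so each
  # window carries the same in-band noise statistics as windows cut from
  # a continuous recording
  stride <- length(t_ms) + 49
  stream <- dspiker:::pink_noise_((n + n_artifacts) * stride + stride,
                                  1000, 1, noise_sd)
  noise_row <- function(i) stream[(i - 1) * stride + seq_along(t_ms)]
  W <- t(vapply(seq_len(n), function(i) {
    shape <- if (types[i] == 1) tpl1 else tpl2
    amps[i] * shape + noise_row(i)
  }, numeric(length(t_ms))))
  if (n_artifacts > 0) {
    art_shape <- exp(-t_ms^2 / 8) - 0.6 * exp(-(t_ms - 6)^2 / 18)
    A <- t(vapply(seq_len(n_artifacts), function(i) {
      artifact_amp * art_shape + noise_row(n + i)
    }, numeric(length(t_ms))))
    W <- rbind(W, A)
    types <- c(types, rep(0L, n_artifacts))
  }
  attr(W, "t_ms") <- t_ms
  attr(W, "fs") <- 1000
  list(W = W, types = types)
}
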