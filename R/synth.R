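#' Build a dentate-spike waveform template
#'
#' Templates are the sum of a Gaussian main lobe and a delayed negative
#' Gaussian lobe, an analytic family chosen so the width metric and the
#' post-peak sum are controllable in closed form. The main-lobe scale is set
#' so that the second-derivative width metric of the noiseless template
#' equals `width_param` (the positive curvature maxima of a Gaussian of
#' scale `sigma` sit at `+/- sigma * sqrt(3)`). The negative lobe is centred
#' at `3 sigma` after the peak and reproduces the post-peak negativity that
#' distinguishes DS2 ("higher and sharper" with a pronounced negative
#' post-peak potential) from DS1.
#'
#' @param ds_type 1 or 2; stored as ground-truth type of the template.
#' @param width_param Target total width in ms (physiological range roughly
#'   10-27 ms). Must be positive.
#' @param post_peak_depth Relative amplitude (<= 0) of the negative lobe
#'   after the peak; more negative for DS2.
#' @param fs Sampling rate of the template time base (Hz).
#' @param span_ms Time span of the sampled shape relative to the peak.
#' @param laminar_profile Optional per-channel gain vector (most superficial
#'   first) attached to the template for multichannel synthesis.
#'
#' @return A `ds_template`: list with `ds_type`, `t_ms`, `shape` (unit peak
#'   at t = 0), `width_param`, `post_peak_depth`, `fs`, `laminar_profile`.
#' @examples
#' tpl <- make_ds_template(2, width_param = 14, post_peak_depth = -0.3)
#' plot(tpl$t_ms, tpl$shape, type = "l", xlab = "ms", ylab = "unit amp.")
#' @export
make_ds_template <- function(ds_type, width_param, post_peak_depth = -0.2,
                             fs = 1000, span_ms = c(-200, 200),
                             laminar_profile = NULL) {
  if (!ds_type %in% c(1, 2)) stop_("`ds_type` must be 1 or 2")
  if (!is.numeric(width_param) || length(width_param) != 1 ||
      is.na(width_param) || width_param <= 0) {
    stop_("`width_param` must be a single positive number (ms)")
  }
  if (post_peak_depth > 0) stop_("`post_peak_depth` must be <= 0")
  t_ms <- seq(span_ms[1], span_ms[2], by = 1000 / fs)
  shape <- ds_shape_fun_(width_param, post_peak_depth)(t_ms)
  structure(
    list(ds_type = as.integer(ds_type), t_ms = t_ms, shape = shape,
         width_param = width_param, post_peak_depth = post_peak_depth,
         fs = fs, laminar_profile = laminar_profile),
    class = "ds_template"
  )
}

# Analytic DS shape: Gaussian main lobe + delayed negative lobe,
# recentred and rescaled so the continuous maximum is exactly 1 at t = 0
# (the negative lobe shifts the raw maximum slightly off zero).
ds_shape_fun_ <- function(width_param, post_peak_depth) {
  sigma <- width_param / (2 * sqrt(3))
  lobe_center <- 3 * sigma
  lobe_sigma <- 1.5 * sigma
  f <- function(t) {
    exp(-t^2 / (2 * sigma^2)) +
      post_peak_depth * exp(-(t - lobe_center)^2 / (2 * lobe_sigma^2))
  }
  opt <- stats::optimize(f, interval = c(-sigma, sigma), maximum = TRUE)
  function(t) f(t + opt$maximum) / opt$objective
}

#' Canonical laminar gain profiles for the two DS types
#'
#' Per-channel gains for a depth-ordered probe (channel 1 most superficial).
#' The profiles are constructed so that the discrete second spatial
#' difference (the CSD) of each has one dominant sink above one dominant
#' source, with the DS1 sink one channel shallower than the DS2 sink --
#' mirroring the outer- vs middle-molecular-layer sink positions that the
#' CSD-based classifier exploits. On the canonical 8-channel probe the DS1
#' sink falls on channel 3 and the DS2 sink on channel 4, with the common
#' source (hilus, where the events are largest) on channel 6. Profiles for
#' other channel counts are linearly interpolated from the 8-channel ones.
#'
#' @param n_channels Number of electrodes (>= 5 for a meaningful CSD;
#'   `n_channels = 1` returns unit gains for single-channel synthesis).
#' @return A list with elements `ds1` and `ds2` (numeric gain vectors),
#'   `target_channel` (hilus channel, unit gain) and `reference_channel`.
#' @export
default_laminar_profiles <- function(n_channels = 8) {
  g1 <- c(0.20, 0.10, -0.25, 0.30, 0.80, 1.00, 0.70, 0.40)
  g2 <- c(0.09, 0.14, 0.27, -0.18, 0.45, 1.00, 0.73, 0.41)
  if (n_channels == 1) {
    return(list(ds1 = 1, ds2 = 1, target_channel = 1L,
                reference_channel = NA_integer_))
  }
  if (n_channels < 5) stop_("need >= 5 channels for a laminar profile")
  if (n_channels != 8) {
    x8 <- seq(0, 1, length.out = 8)
    xn <- seq(0, 1, length.out = n_channels)
    g1 <- approx(x8, g1, xout = xn)$y
    g2 <- approx(x8, g2, xout = xn)$y
  }
  list(ds1 = g1, ds2 = g2, target_channel = which.max(g1),
       reference_channel = 1L)
}

#' Configuration for the synthetic laminar-LFP generator
#'
#' Defaults emulate the validation conditions of the analysis pipeline: a
#' 30-min, 1 kHz, 8-channel session with 500 events of each DS type at a
#' mean peak amplitude well above 1 mV, pink (1/f) background noise, and
#' alternating delta-on (slow-wave, 3 Hz) / delta-off (theta, 7 Hz) epochs.
#' Events are placed only inside delta-on epochs, reflecting the
#' predominance of DSs during periods of increased delta power.
#'
#' @param duration_s Session length in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of depth-ordered channels (1 or >= 5).
#' @param n_events Integer vector `c(ds1, ds2)`: number of events per type.
#'   Alternatively give `rate_per_min` (per type) and counts are derived.
#' @param rate_per_min Optional per-type event rates (events/min); overrides
#'   `n_events` when supplied.
#' @param amplitude_mean_mv,amplitude_sd_mv Per-type mean and sd of the
#'   log-normal peak-amplitude distribution (mV), truncated to its own
#'   Tukey fences so no legitimate event is an amplitude outlier.
#' @param noise_sd Per-channel noise standard deviation (mV).
#' @param noise_alpha Spectral exponent of the 1/f^alpha background noise.
#' @param delta_freq,delta_amp Delta oscillation frequency (Hz) and
#'   amplitude (mV) during delta-on epochs.
#' @param delta_on_s,delta_off_s Alternating epoch durations (s), starting
#'   with an on epoch.
#' @param theta_freq,theta_amp Oscillation present during delta-off epochs,
#'   emulating the theta state that replaces slow-wave activity.
#' @param artifact_rate_per_min,artifact_amplitude_mv Rate and amplitude of
#'   common-mode artifact transients (0 disables them).
#' @param width_ms,post_peak_depth Per-type template parameters, see
#'   [make_ds_template()].
#' @param width_jitter_rel,depth_jitter_rel Relative (log-normal) sd of the
#'   per-event width and post-peak-depth jitter around the type template;
#'   real event waveforms vary smoothly from trial to trial, and this
#'   within-type shape variability is what mixture clustering of a
#'   single-type population splits on.
#' @param min_spacing_ms Minimum spacing between ground-truth events.
#' @param edge_margin_s Events are kept at least this far from the signal
#'   edges.
#' @param events_in_delta_only Place events only inside delta-on epochs.
#' @param seed RNG seed; the seed fully determines the output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 1800, fs = 1000, n_channels = 8,
                         n_events = c(500, 500), rate_per_min = NULL,
                         amplitude_mean_mv = c(1.5, 1.5),
                         amplitude_sd_mv = c(0.25, 0.25),
                         noise_sd = 0.1, noise_alpha = 1,
                         delta_freq = 3, delta_amp = 0.3,
                         delta_on_s = 120, delta_off_s = 60,
                         theta_freq = 7, theta_amp = 0.15,
                         artifact_rate_per_min = 0,
                         artifact_amplitude_mv = 7.5,
                         width_ms = c(22, 14),
                         post_peak_depth = c(-0.12, -0.3),
                         width_jitter_rel = 0.08, depth_jitter_rel = 0.15,
                         min_spacing_ms = 250, edge_margin_s = 0.5,
                         events_in_delta_only = TRUE, seed = 1) {
  if (fs <= 0) stop_("`fs` must be positive")
  if (duration_s <= 0) stop_("`duration_s` must be positive")
  if (!is.null(rate_per_min)) {
    if (any(rate_per_min < 0)) stop_("rates must be >= 0")
    n_events <- round(rep_len(rate_per_min, 2) * duration_s / 60)
  }
  n_events <- as.integer(rep_len(n_events, 2))
  if (any(n_events < 0)) stop_("event counts must be >= 0")
  cfg <- list(
    duration_s = duration_s, fs = fs, n_channels = n_channels,
    n_events = n_events,
    amplitude_mean_mv = rep_len(amplitude_mean_mv, 2),
    amplitude_sd_mv = rep_len(amplitude_sd_mv, 2),
    noise_sd = noise_sd, noise_alpha = noise_alpha,
    delta_freq = delta_freq, delta_amp = delta_amp,
    delta_on_s = delta_on_s, delta_off_s = delta_off_s,
    theta_freq = theta_freq, theta_amp = theta_amp,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_amplitude_mv = artifact_amplitude_mv,
    width_ms = rep_len(width_ms, 2),
    post_peak_depth = rep_len(post_peak_depth, 2),
    width_jitter_rel = width_jitter_rel,
    depth_jitter_rel = depth_jitter_rel,
    min_spacing_ms = min_spacing_ms, edge_margin_s = edge_margin_s,
    events_in_delta_only = events_in_delta_only, seed = seed
  )
  class(cfg) <- "synth_config"
  cfg
}

# Pink (1/f^alpha) Gaussian noise via spectral shaping. The amplitude
# spectrum is flattened below 0.5 Hz so the baseline does not wander on
# the scale of the event amplitudes, and rolled off above 300 Hz to mimic
# the anti-aliasing / hardware filtering of LFP acquired at (or
# downsampled to) 1 kHz, which carries no power near the Nyquist rate.
pink_noise_ <- function(n, fs, alpha, sd_target, f_high = 300) {
  white <- rnorm(n)
  x <- fft(white)
  freq <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freq <- pmin(freq, fs - freq)          # two-sided frequency axis
  scale <- pmax(freq, 0.5)^(-alpha / 2)
  scale <- scale / (1 + (freq / f_high)^8)  # steep anti-aliasing roll-off
  scale[1] <- 0                          # remove DC
  out <- Re(fft(x * scale, inverse = TRUE)) / n
  out * (sd_target / sd(out))
}

# Delta-on mask per sample for an alternating on/off schedule, with 1-s
# cosine ramps at the transitions.
delta_schedule_ <- function(n, fs, on_s, off_s) {
  period <- round((on_s + off_s) * fs)
  phase <- (seq_len(n) - 1) %% period
  mask <- as.numeric(phase < round(on_s * fs))
  ramp_n <- min(round(fs), n)
  kernel <- rep(1 / ramp_n, ramp_n)
  smooth <- stats::filter(c(rep(mask[1], ramp_n), mask, rep(mask[n], ramp_n)),
                          kernel, sides = 2)
  as.numeric(smooth[(ramp_n + 1):(ramp_n + n)])
}

# Draw log-normal amplitudes with the requested mean/sd, redrawing values
# outside the Tukey fences of the initial draw so the outlier filter never
# eats legitimate events. `margin` shrinks the truncation interval to leave
# room for the background (state rhythm + noise) carried by the raw LFP at
# the peak: the *measured* amplitude, not the injected one, must stay
# inside the fences of the detected population.
draw_amplitudes_ <- function(n, mean_mv, sd_mv, margin = 0) {
  if (n == 0) return(numeric(0))
  cv2 <- (sd_mv / mean_mv)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean_mv) - sdlog^2 / 2
  amp <- rlnorm(n, meanlog, sdlog)
  q <- quantile(amp, c(0.25, 0.75), names = FALSE)
  fences <- c(q[1] - 1.5 * diff(q) + margin, q[2] + 1.5 * diff(q) - margin)
  if (fences[1] >= fences[2]) {
    stop_("amplitude spread too narrow for the background margin")
  }
  for (i in 1:20) {
    bad <- amp < fences[1] | amp > fences[2]
    if (!any(bad)) break
    amp[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  amp[amp < fences[1]] <- fences[1]
  amp[amp > fences[2]] <- fences[2]
  amp
}

# Place `n` event samples inside `allowed` (logical per sample), pairwise
# spacing >= min_gap samples. Rejection sampling against the running set.
place_events_ <- function(n, allowed, min_gap) {
  pool <- which(allowed)
  if (n == 0) return(integer(0))
  if (length(pool) < n) stop_("duration too short to place requested events")
  placed <- integer(0)
  attempts <- 0L
  max_attempts <- n * 500L
  while (length(placed) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_("duration too short to place requested events with spacing ",
            min_gap, " samples")
    }
    cand <- pool[sample.int(length(pool), 1)]
    if (length(placed) == 0 || min(abs(placed - cand)) >= min_gap) {
      placed <- c(placed, cand)
    }
  }
  sort(placed)
}

#' Synthesize a laminar LFP recording with ground-truth dentate spikes
#'
#' Generates per-channel signal = laminar-profile-scaled DS templates +
#' 1/f background noise + state oscillations (delta during on epochs, theta
#' during off epochs, common across channels) + optional common-mode
#' artifacts. The RNG seed in the config fully determines the output.
#'
#' @param config A [synth_config()].
#' @return A list with `recording` (an [lfp_recording()]), `truth` (tibble
#'   with `peak_sample`, `type`, `is_artifact`), `target_channel`,
#'   `reference_channel`, and the per-type `templates`.
#' @examples
#' out <- synthesize_recording(synth_config(duration_s = 60, n_events = c(10, 10)))
#' out$recording
#' head(out$truth)
#' @export
synthesize_recording <- function(config) {
  if (!inherits(config, "synth_config")) stop_("expected a `synth_config`")
  cfg <- config
  n <- round(cfg$duration_s * cfg$fs)
  profiles <- default_laminar_profiles(cfg$n_channels)
  with_seed_(cfg$seed, {
    templates <- list(
      make_ds_template(1, cfg$width_ms[1], cfg$post_peak_depth[1],
                       fs = cfg$fs, span_ms = c(-100, 150),
                       laminar_profile = profiles$ds1),
      make_ds_template(2, cfg$width_ms[2], cfg$post_peak_depth[2],
                       fs = cfg$fs, span_ms = c(-100, 150),
                       laminar_profile = profiles$ds2)
    )
    # background: independent pink noise per channel + common state rhythms
    samples <- matrix(0, nrow = cfg$n_channels, ncol = n)
    for (ch in seq_len(cfg$n_channels)) {
      samples[ch, ] <- pink_noise_(n, cfg$fs, cfg$noise_alpha, cfg$noise_sd)
    }
    mask <- delta_schedule_(n, cfg$fs, cfg$delta_on_s, cfg$delta_off_s)
    t_s <- (seq_len(n) - 1) / cfg$fs
    modulation <- 1 + 0.25 * sin(2 * pi * 0.05 * t_s + runif(1, 0, 2 * pi))
    delta_phase_sin <- sin(2 * pi * cfg$delta_freq * t_s + runif(1, 0, 2 * pi))
    delta <- cfg$delta_amp * modulation * delta_phase_sin * mask
    theta <- cfg$theta_amp *
      sin(2 * pi * cfg$theta_freq * t_s + runif(1, 0, 2 * pi)) * (1 - mask)
    state <- delta + theta
    samples <- sweep(samples, 2, state, "+")

    # event placement: inside delta-on epochs (away from the ramps), on the
    # depolarized crest of the delta cycle (UP-state-like), clear of the
    # signal edges, pairwise spacing >= min_spacing_ms
    margin <- round(cfg$edge_margin_s * cfg$fs)
    allowed <- if (cfg$events_in_delta_only) {
      mask > 0.95 & delta_phase_sin > 0.7
    } else {
      rep(TRUE, n)
    }
    allowed[seq_len(min(margin, n))] <- FALSE
    allowed[seq.int(max(1, n - margin + 1), n)] <- FALSE
    n_total <- sum(cfg$n_events)
    peaks <- place_events_(n_total, allowed,
                           ms_to_samples_(cfg$min_spacing_ms, cfg$fs))
    types <- sample(rep.int(c(1L, 2L), cfg$n_events))
    amp <- numeric(n_total)
    bg_margin <- cfg$delta_amp / 2 + 2 * cfg$noise_sd
    for (k in 1:2) {
      amp[types == k] <- draw_amplitudes_(sum(types == k),
                                          cfg$amplitude_mean_mv[k],
                                          cfg$amplitude_sd_mv[k],
                                          margin = bg_margin)
    }
    # per-event smooth shape variability: event widths and post-peak
    # depths jitter around the type template, as real event waveforms do;
    # peak times are continuous (uniform sub-sample offset), since analog
    # events are not locked to the sampling grid
    width_i <- cfg$width_ms[types] *
      exp(rnorm(n_total, 0, cfg$width_jitter_rel))
    depth_i <- cfg$post_peak_depth[types] *
      exp(rnorm(n_total, 0, cfg$depth_jitter_rel))
    subsample_u <- runif(n_total, -0.5, 0.5) * 1000 / cfg$fs
    tpl_grid <- ms_to_samples_(seq(-100, 150, by = 1000 / cfg$fs), cfg$fs)
    # add laminar-scaled event waveforms
    for (i in seq_len(n_total)) {
      shape_fun <- ds_shape_fun_(width_i[i], depth_i[i])
      t_eval <- tpl_grid * 1000 / cfg$fs - subsample_u[i]
      idx <- peaks[i] + tpl_grid
      keep <- idx >= 1 & idx <= n
      gains <- profiles[[paste0("ds", types[i])]]
      samples[, idx[keep]] <- samples[, idx[keep]] +
        outer(gains, amp[i] * shape_fun(t_eval[keep]))
    }
    truth <- tibble(peak_sample = peaks, type = types,
                    is_artifact = FALSE)

    recording <- lfp_recording(samples, fs = cfg$fs)
    if (cfg$artifact_rate_per_min > 0) {
      art <- embed_artifacts(recording, cfg$artifact_rate_per_min,
                             cfg$artifact_amplitude_mv,
                             seed = sample.int(.Machine$integer.max, 1),
                             avoid_samples = peaks)
      recording <- art$recording
      truth <- dplyr::bind_rows(
        truth,
        tibble(peak_sample = art$artifact_samples, type = NA_integer_,
               is_artifact = TRUE)
      )
    }
    truth <- dplyr::arrange(truth, .data$peak_sample)
    list(recording = recording, truth = truth,
         target_channel = profiles$target_channel,
         reference_channel = profiles$reference_channel,
         templates = templates, delta_mask = mask)
  })
}

#' Insert common-mode artifact transients into a recording
#'
#' Artifacts are sharp biphasic deflections with an identical waveform on
#' every channel (common mode), so subtracting a reference channel cancels
#' them exactly while leaving laminar-graded physiological events intact.
#'
#' @param recording An [lfp_recording()].
#' @param rate_per_min Artifact rate (>= 0; 0 returns the recording
#'   unchanged).
#' @param amplitude_mv Artifact peak amplitude in mV.
#' @param seed RNG seed for placement.
#' @param avoid_samples Sample indices (e.g. true event peaks) that
#'   artifacts must stay clear of.
#' @param min_gap_ms Minimum distance from `avoid_samples` and between
#'   artifacts.
#' @return A list with the modified `recording` and sorted
#'   `artifact_samples`.
#' @export
embed_artifacts <- function(recording, rate_per_min, amplitude_mv = 5,
                            seed = 1, avoid_samples = integer(0),
                            min_gap_ms = 300) {
  assert_lfp_(recording)
  if (rate_per_min < 0) stop_("`rate_per_min` must be >= 0")
  if (rate_per_min == 0) {
    return(list(recording = recording, artifact_samples = integer(0)))
  }
  fs <- recording$fs
  n <- n_samples_(recording)
  n_art <- max(1L, round(rate_per_min * n / fs / 60))
  with_seed_(seed, {
    gap <- ms_to_samples_(min_gap_ms, fs)
    margin <- ms_to_samples_(300, fs)
    allowed <- rep(TRUE, n)
    allowed[seq_len(min(margin, n))] <- FALSE
    allowed[seq.int(max(1, n - margin + 1), n)] <- FALSE
    for (s in avoid_samples) {
      lo <- max(1, s - gap); hi <- min(n, s + gap)
      allowed[lo:hi] <- FALSE
    }
    placed <- place_events_(n_art, allowed, gap)
    t_ms <- seq(-20, 30, by = 1000 / fs)
    shape <- exp(-t_ms^2 / 8) - 0.6 * exp(-(t_ms - 6)^2 / 18)
    shape <- shape / max(shape)
    samples <- recording$samples
    for (s in placed) {
      idx <- s + ms_to_samples_(t_ms, fs)
      keep <- idx >= 1 & idx <= n
      samples[, idx[keep]] <- samples[, idx[keep]] +
        matrix(amplitude_mv * shape[keep], nrow = nrow(samples),
               ncol = sum(keep), byrow = TRUE)
    }
    list(recording = lfp_recording(samples, fs = fs,
                                   channel_ids = recording$channel_ids,
                                   units = recording$units),
         artifact_samples = placed)
  })
}
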