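test_that("reference subtraction is elementwise and validated", {
  x <- rnorm(100)
  expect_equal(subtract_reference(x, x), rep(0, 100))
  expect_equal(subtract_reference(x, rep(0, 100)), x)
  expect_error(subtract_reference(x, rnorm(50)), "length")
})

test_that("bandpass filter passes the band and kills drift and DC", {
  t <- (0:9999) / 1000
  # oracle: the designed filter's own gain at 100 Hz, squared because the
  # filter runs forward and backward
  bf <- signal::butter(4, c(1, 200) / 500, type = "pass")
  z <- exp(-1i * 2 * pi * 100 / 1000 * (seq_along(bf$b) - 1))
  h100 <- Mod(sum(bf$b * z) / sum(bf$a * z))^2
  in_band <- bandpass_filter(sin(2 * pi * 100 * t), 1000)
  # RMS amplitude: 100 Hz at 1 kHz is 10 samples/cycle, so the sampled
  # maximum understates the amplitude by cos(pi/10)
  amp <- sqrt(2 * mean(in_band[2001:8000]^2))
  expect_lt(abs(amp - h100), 0.01)
  expect_gt(h100, 0.95)
  drift <- bandpass_filter(sin(2 * pi * 0.1 * t), 1000)
  expect_lt(max(abs(drift[4000:6000])), 0.1)   # > 90% attenuation
  # DC removed once the edge transient of the 1-Hz high-pass has decayed
  dc <- bandpass_filter(rep(2, 20000), 1000)
  expect_lt(max(abs(dc[9000:11000])), 1e-3)
  expect_error(bandpass_filter(rnorm(100), 1000, band = c(200, 100)),
               "invalid band")
  expect_error(bandpass_filter(rnorm(100), 300, band = c(1, 200)), "fs")
})

test_that("peak detection thresholds at 7x median |x| and spaces peaks", {
  # a pure sinusoid never crosses 7 * median|A sin| = 7A sin(pi/4)
  t <- (0:19999) / 1000
  expect_length(detect_peaks(sin(2 * pi * 5 * t), 1000), 0)
  expect_length(detect_peaks(rep(0, 1000), 1000), 0)
  # two super-threshold bumps 30 ms apart: only the larger survives
  x <- rnorm(4000, sd = 0.01)
  bump <- exp(-((-30:30)^2) / 18)
  x[1000 + (-30:30)] <- x[1000 + (-30:30)] + 2 * bump
  x[1030 + (-30:30)] <- x[1030 + (-30:30)] + 3 * bump
  peaks <- detect_peaks(x, 1000)
  expect_length(peaks, 1)
  expect_lt(abs(peaks - 1030), 3)
})

test_that("peak offset correction finds the raw argmax with earliest-tie rule", {
  raw <- rep(0, 200)
  raw[100] <- 1
  expect_equal(correct_peak_offsets(raw, 100L)$offset_ms, 0)
  out <- correct_peak_offsets(raw, 99L)
  expect_equal(out$peak_sample, 100L)
  expect_equal(out$offset_ms, 1)
  # two tied raw maxima: earliest index wins
  raw[104] <- 1
  expect_equal(correct_peak_offsets(raw, 102L)$peak_sample, 100L)
  # peak too close to the edge is dropped with a warning
  expect_warning(out2 <- correct_peak_offsets(raw, c(5L, 100L)), "edge")
  expect_equal(out2$peak_sample, 100L)
})

test_that("Tukey fences follow the hand-computed quartile rule", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_equal(remove_amplitude_outliers(c(1, 2, 3, 4, 100)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # all-equal amplitudes: degenerate fences keep everything
  expect_true(all(remove_amplitude_outliers(rep(2, 10))))
  # a value exactly on the fence is kept (closed interval)
  expect_true(all(remove_amplitude_outliers(c(1, 2, 3, 4, 7))))
  # fewer than 4 events: no-op with warning
  expect_warning(keep <- remove_amplitude_outliers(c(1, 100)), "fewer")
  expect_true(all(keep))
})

test_that("detection recovers synthetic ground truth with few false positives", {
  fx <- small_two_type_()
  truth <- fx$truth
  catalog <- fx$catalog
  dist_to_det <- vapply(truth$peak_sample, function(p) {
    min(abs(catalog$peak_sample - p))
  }, numeric(1))
  expect_gte(mean(dist_to_det <= 2), 0.95)
  fp <- sum(vapply(catalog$peak_sample, function(p) {
    min(abs(truth$peak_sample - p)) > 2
  }, logical(1)))
  expect_lte(fp / nrow(truth), 0.02)
})

test_that("detection invariants hold on the synthetic catalog", {
  fx <- small_two_type_()
  catalog <- fx$catalog
  raw <- fx$recording$samples[fx$target_channel, ]
  # spacing >= 50 ms
  expect_gte(min(diff(catalog$peak_sample)), 50)
  # every peak is the raw argmax of its +-10 ms window
  for (p in catalog$peak_sample) {
    expect_equal(raw[p], max(raw[(p - 10):(p + 10)]))
  }
  # no surviving amplitude outside the fences of the pre-filter population
  pre <- detect_dentate_spikes(fx$recording, fx$target_channel,
                               fx$reference_channel,
                               detection_params(use_tukey_filter = FALSE))
  q <- quantile(pre$amplitude_mv, c(0.25, 0.75), names = FALSE)
  iqr <- diff(q)
  expect_true(all(catalog$amplitude_mv >= q[1] - 1.5 * iqr &
                    catalog$amplitude_mv <= q[2] + 1.5 * iqr))
})

test_that("raising the threshold multiplier never increases detections", {
  fx <- small_two_type_()
  n_prev <- Inf
  for (mult in c(5, 7, 9, 12)) {
    p <- detection_params(threshold_multiplier = mult)
    n <- nrow(detect_dentate_spikes(fx$recording, fx$target_channel,
                                    fx$reference_channel, p))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("the orchestrator equals the composition of its stages", {
  fx <- small_two_type_()
  rec <- fx$recording
  p <- detection_params()
  raw <- rec$samples[fx$target_channel, ]
  ref <- rec$samples[fx$reference_channel, ]
  filt <- bandpass_filter(subtract_reference(raw, ref), 1000, p$band,
                          p$filter_order)
  peaks <- detect_peaks(filt, 1000, p)
  corr <- correct_peak_offsets(raw, peaks, 1000, p$offset_window_ms)
  keep <- !duplicated(corr$peak_sample)
  ps <- corr$peak_sample[keep]
  ps <- dspiker:::enforce_spacing_(ps, raw[ps], 50L)
  ps <- ps[ps > 200 & ps <= length(raw) - 200]
  ps <- ps[remove_amplitude_outliers(raw[ps])]
  expect_identical(fx$catalog$peak_sample, as.integer(ps))
  expect_identical(fx$catalog$amplitude_mv, raw[ps])
})

test_that("detection rejects non-canonical rates and bad channels", {
  rec <- lfp_recording(matrix(rnorm(4000), 2), fs = 2000)
  expect_error(detect_dentate_spikes(rec, 1), "1 kHz")
  rec2 <- lfp_recording(matrix(rnorm(4000), 2), fs = 1000)
  expect_error(detect_dentate_spikes(rec2, 5), "out of range")
})
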