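test_that("DS templates peak at 1 and carry the type contrast", {
  tpl1 <- make_ds_template(1, 22, -0.12)
  tpl2 <- make_ds_template(2, 14, -0.3)
  for (tpl in list(tpl1, tpl2)) {
    expect_equal(tpl$shape[tpl$t_ms == 0], 1)
    expect_equal(which.max(tpl$shape), which(tpl$t_ms == 0))
  }
  # type 2 is sharper with a more negative post-peak sum (10..50 ms)
  s1 <- sum(tpl1$shape[tpl1$t_ms >= 10 & tpl1$t_ms <= 50])
  s2 <- sum(tpl2$shape[tpl2$t_ms >= 10 & tpl2$t_ms <= 50])
  expect_lt(s2, s1)
  expect_error(make_ds_template(1, 0), "positive")
  expect_error(make_ds_template(3, 10), "1 or 2")
})

test_that("template second derivative has two concavity maxima flanking the peak", {
  for (w in c(12, 18, 26)) {
    tpl <- make_ds_template(1, w, -0.15)
    d2 <- second_derivative(mw_(tpl$t_ms, tpl$shape))
    sel <- d2$t_ms >= -15 & d2$t_ms <= 15
    v <- d2$amplitude[sel]; tt <- d2$t_ms[sel]
    peaks <- which(diff(sign(diff(v))) < 0) + 1
    prominent <- peaks[v[peaks] > 0.25 * max(v[peaks])]
    expect_length(prominent, 2)
    expect_lt(tt[prominent[1]], 0)
    expect_gt(tt[prominent[2]], 0)
  }
})

test_that("template width metric matches the constructed width and the vote rule", {
  tpl1 <- make_ds_template(1, 22, -0.12)
  w1 <- measure_width(mw_(tpl1$t_ms, tpl1$shape))
  expect_gt(w1$width_ms, 19)  # voted DS1
  expect_equal(vote_single_type(w1)$voted_type, 1L)
  tpl2 <- make_ds_template(2, 14, -0.3)
  w2 <- measure_width(mw_(tpl2$t_ms, tpl2$shape))
  expect_lt(w2$width_ms, 19)
  expect_equal(vote_single_type(w2)$voted_type, 2L)
})

test_that("synthesis is fully determined by the seed", {
  cfg <- synth_config(duration_s = 30, n_events = c(5, 5), seed = 7)
  a <- synthesize_recording(cfg)
  b <- synthesize_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  # different seed differs
  c <- synthesize_recording(synth_config(duration_s = 30,
                                         n_events = c(5, 5), seed = 8))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("zero rates give a pure background recording", {
  out <- synthesize_recording(synth_config(duration_s = 30,
                                           n_events = c(0, 0)))
  expect_equal(nrow(out$truth), 0)
  expect_equal(dim(out$recording$samples), c(8, 30000))
})

test_that("ground-truth placement respects spacing and edge margins", {
  cfg <- synth_config(duration_s = 120, n_events = c(30, 30), seed = 3)
  out <- synthesize_recording(cfg)
  expect_gte(min(diff(out$truth$peak_sample)), 50)
  expect_gte(min(diff(out$truth$peak_sample)), cfg$min_spacing_ms)
  expect_gte(min(out$truth$peak_sample), 200)
  expect_lte(max(out$truth$peak_sample), 120000 - 200)
  expect_true(!is.unsorted(out$truth$peak_sample, strictly = TRUE))
})

test_that("too-dense event requests fail", {
  expect_error(
    synthesize_recording(synth_config(duration_s = 5, n_events = c(500, 0))),
    "duration too short"
  )
})

test_that("laminar profiles put the type sinks at distinct depths, DS1 shallower", {
  prof <- default_laminar_profiles(8)
  csd1 <- csd_profile(prof$ds1)
  csd2 <- csd_profile(prof$ds2)
  sink1 <- which.min(csd1)
  sink2 <- which.min(csd2)
  expect_lt(sink1, sink2)                 # DS1 sink shallower
  expect_lt(csd1[sink1], 0)               # real sinks
  expect_lt(csd2[sink2], 0)
  # one dominant sink above one dominant source in each profile
  for (csd in list(csd1, csd2)) {
    src <- which.max(csd)
    expect_gt(src, which.min(csd))        # source below the sink
    expect_gt(csd[src], 0)
  }
})

test_that("noiseless mean-event CSD recovers the configured sinks", {
  out <- synthesize_recording(
    synth_config(duration_s = 120, n_events = c(20, 20), seed = 5,
                 noise_sd = 1e-6, delta_amp = 0, theta_amp = 0)
  )
  csd <- csd_matrix(out$recording, out$truth)
  for (k in 1:2) {
    m <- colMeans(csd[out$truth$type == k, , drop = FALSE])
    prof <- default_laminar_profiles(8)[[paste0("ds", k)]]
    expect_equal(which.min(m), which.min(csd_profile(prof)))
  }
})

test_that("artifacts are common mode and cancel under reference subtraction", {
  base <- synthesize_recording(synth_config(duration_s = 60,
                                            n_events = c(0, 0), seed = 2))
  # rate 0 leaves the recording untouched
  same <- embed_artifacts(base$recording, 0)
  expect_identical(same$recording$samples, base$recording$samples)
  art <- embed_artifacts(base$recording, rate_per_min = 5,
                         amplitude_mv = 5, seed = 11)
  expect_gt(length(art$artifact_samples), 0)
  # identical waveform on every channel
  s <- art$recording$samples
  delta <- s - base$recording$samples
  for (ch in 2:nrow(s)) expect_equal(delta[ch, ], delta[1, ])
  # reference subtraction removes them below the detection threshold
  resid <- subtract_reference(s[6, ], s[1, ])
  filt <- bandpass_filter(resid, 1000)
  thr <- 7 * median(abs(filt))
  expect_lt(max(filt[art$artifact_samples]), thr)
})
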