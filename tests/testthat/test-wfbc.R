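test_that("feature windows are the 31 samples around the peak", {
  x <- rnorm(2000)
  x[1000] <- 4
  W <- extract_feature_windows(x, 1000L)
  expect_equal(ncol(W), 31)
  expect_equal(W[1, 16], 4)
  expect_warning(W2 <- extract_feature_windows(x, c(5L, 1000L)), "edge")
  expect_equal(nrow(W2), 1)
})

test_that("artifact clusters below 5% of the total are excluded iteratively", {
  fx <- template_matrix_(485, 485, n_artifacts = 30, seed = 6)
  t_ms <- attr(fx$W, "t_ms")
  feats <- fx$W[, t_ms >= -15 & t_ms <= 15]
  cl <- cluster_waveforms(feats, seed = 1)
  is_art <- fx$types == 0
  expect_gte(mean(cl$cluster[is_art] == "excluded"), 0.9)
  expect_lt(mean(cl$cluster[!is_art] == "excluded"), 0.01)
  expect_lte(cl$n_iterations, 3)
  # loop bound invariant: never more than ceil(1 / min_fraction)
  expect_lte(cl$n_iterations, ceiling(1 / 0.05))
  # final clusters both between 5% and 95% of the total
  frac <- table(cl$cluster[cl$cluster != "excluded"]) / length(cl$cluster)
  expect_true(all(frac >= 0.05 & frac <= 0.95))
})

test_that("clean two-population input clusters in one round with a warning below 500", {
  fx <- template_matrix_(300, 300, seed = 7)
  t_ms <- attr(fx$W, "t_ms")
  feats <- fx$W[, t_ms >= -15 & t_ms <= 15]
  cl <- cluster_waveforms(feats, seed = 2)
  expect_equal(cl$n_iterations, 1)
  expect_false(any(cl$cluster == "excluded"))
  small <- feats[1:100, ]
  expect_warning(cluster_waveforms(small, seed = 1), "500")
  expect_error(cluster_waveforms(feats[1, , drop = FALSE], seed = 1),
               "at least 2")
})

test_that("post-peak sum assigns DS2 to the more negative tail", {
  t <- -200:200
  flat <- mw_(t, exp(-t^2 / 80))
  lobed <- mw_(t, exp(-t^2 / 80) - 0.4 * exp(-(t - 25)^2 / 200))
  map <- assign_types_by_postpeak(flat, lobed)
  expect_equal(map$type_of, c(A = 1L, B = 2L))
  expect_false(map$tie)
  expect_equal(assign_types_by_postpeak(lobed, flat)$type_of,
               c(A = 2L, B = 1L))
  # synthetic templates: the type-2 template is the DS2 cluster
  tpl1 <- make_ds_template(1, 22, -0.12)
  tpl2 <- make_ds_template(2, 14, -0.3)
  map2 <- assign_types_by_postpeak(mw_(tpl1$t_ms, tpl1$shape),
                                   mw_(tpl2$t_ms, tpl2$shape))
  expect_equal(map2$type_of, c(A = 1L, B = 2L))
  # exact tie is flagged
  tie <- assign_types_by_postpeak(flat, flat)
  expect_true(tie$tie)
})

test_that("dissimilarity index is a symmetric pseudo-distance in [0, 1]", {
  tpl1 <- make_ds_template(1, 22, -0.12)
  tpl2 <- make_ds_template(2, 14, -0.3)
  a <- mw_(tpl1$t_ms, tpl1$shape)
  b <- mw_(tpl2$t_ms, tpl2$shape)
  expect_equal(dissimilarity_index(a, a), 0)
  di <- dissimilarity_index(a, b)
  expect_equal(di, dissimilarity_index(b, a))
  expect_gt(di, 0.06)   # distinct types stay distinct
  expect_lte(di, 1)
  expect_error(dissimilarity_index(a, mw_(tpl2$t_ms[1:100], tpl2$shape[1:100])),
               "cover|differ")
  flat <- mw_(-200:200, rep(0, 401))
  expect_error(dissimilarity_index(flat, a), "degenerate")
})

test_that("random halves of one template population fall below the DI threshold", {
  fx <- template_matrix_(1000, 0, seed = 8)
  dis <- vapply(1:10, function(s) {
    set.seed(s)
    g <- sample(c(TRUE, FALSE), nrow(fx$W), replace = TRUE)
    Wa <- fx$W[g, , drop = FALSE]; attr(Wa, "t_ms") <- attr(fx$W, "t_ms")
    Wb <- fx$W[!g, , drop = FALSE]; attr(Wb, "t_ms") <- attr(fx$W, "t_ms")
    dissimilarity_index(mean_waveform(Wa, fs = 1000),
                        mean_waveform(Wb, fs = 1000))
  }, numeric(1))
  expect_gte(sum(dis <= 0.06), 9)
})

test_that("the width vote follows the two-of-three rule", {
  row <- function(w, s, e) tibble::tibble(width_ms = w, start_ms = s, end_ms = e)
  expect_equal(vote_single_type(row(21, -10.5, 10.5))$voted_type, 1L)
  expect_equal(vote_single_type(row(14, -7, 7))$voted_type, 2L)
  expect_equal(vote_single_type(row(20, -9, 9))$voted_type, 2L)  # 1 vs 2
  v <- vote_single_type(row(21, -10.5, 9))
  expect_equal(v$voted_type, 1L)                                 # 2 vs 1
  expect_named(v$votes, c("width", "start", "end"))
})

test_that("WFbC recovers ground-truth types on synthetic data, deterministically", {
  fx <- small_two_type_()
  cls <- classify_wfbc(fx$recording, fx$catalog, channel = fx$target_channel,
                       seed = 5)
  ok <- !cls$excluded & !is.na(fx$catalog_true_type)
  expect_gte(mean(cls$label[ok] == fx$catalog_true_type[ok]), 0.9)
  expect_false(attr(cls, "merged_single_type"))
  expect_gt(attr(cls, "di"), 0.06)
  again <- classify_wfbc(fx$recording, fx$catalog,
                         channel = fx$target_channel, seed = 5)
  expect_identical(cls$label, again$label)
  # empty catalog passes through
  empty <- classify_wfbc(fx$recording, fx$catalog[0, ],
                         channel = fx$target_channel)
  expect_equal(nrow(empty), 0)
})

test_that("a single-type population is merged and typed by the width vote", {
  fx <- template_matrix_(0, 900, seed = 9)
  core <- suppressWarnings(
    dspiker:::wfbc_core_(fx$W, wfbc_params(), seed = 1,
                         check_single_type = TRUE)
  )
  expect_true(core$merged_single_type)
  expect_lte(core$di, 0.06)
  expect_equal(core$voted_type, 2L)
  expect_true(all(core$labels[!core$excluded] == 2L))
})

test_that("window sweep reports one row per window across seeds", {
  fx <- small_two_type_()
  ref <- classify_csdbc(fx$recording, fx$catalog, seed = 1)$label
  sweep <- window_size_sweep(fx$recording, fx$catalog, ref,
                             windows = list(c(-15, 15), c(-5, 5)),
                             channel = fx$target_channel, n_seeds = 2,
                             seed = 1)
  expect_equal(nrow(sweep), 2)
  expect_true(all(sweep$mean_accuracy >= 0 & sweep$mean_accuracy <= 1))
  expect_true(all(sweep$n_runs == 2))
  expect_error(window_size_sweep(fx$recording, fx$catalog, ref,
                                 windows = list(),
                                 channel = fx$target_channel), "empty")
})

test_that("subsampling experiment is deterministic and reports merges", {
  fx <- template_matrix_(400, 400, seed = 10)
  tl <- fx$types
  res <- suppressWarnings(
    subsample_experiment(fx$W, tl, totals = 200, ds2_proportions = 0.5,
                         n_rounds = 2, seed = 3)
  )
  expect_equal(nrow(res), 1)
  res2 <- suppressWarnings(
    subsample_experiment(fx$W, tl, totals = 200, ds2_proportions = 0.5,
                         n_rounds = 2, seed = 3)
  )
  expect_identical(res, res2)
  expect_true(res$merged_fraction >= 0 & res$merged_fraction <= 1)
  expect_error(
    suppressWarnings(subsample_experiment(fx$W, tl, totals = 2000,
                                          ds2_proportions = 0.5,
                                          n_rounds = 1)),
    "insufficient"
  )
})

test_that("tidy and glance summarise classifications", {
  fx <- small_two_type_()
  cls <- classify_wfbc(fx$recording, fx$catalog, channel = fx$target_channel)
  td <- generics::tidy(cls)
  expect_true(all(c("peak_sample", "label", "method") %in% names(td)))
  expect_equal(nrow(td), nrow(cls))
  gl <- generics::glance(cls)
  expect_equal(gl$n_events, nrow(cls))
  expect_equal(gl$method, "WFbC")
  expect_equal(gl$n_ds1 + gl$n_ds2 + gl$n_excluded, nrow(cls))
})
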