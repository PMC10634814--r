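test_that("CSD profile implements the discrete Poisson formula", {
  expect_equal(csd_profile(c(0, 1, 0)), 2)    # source at the middle
  expect_equal(csd_profile(c(1, 0, 1)), -2)   # sink
  expect_equal(csd_profile(c(0, 1, 2, 3)), c(0, 0))
  expect_equal(csd_profile(c(0, 1, 0), sigma = 2), 4)
  expect_error(csd_profile(c(1, 2)), "3 channels")
  # property: affine-in-depth potentials have identically zero CSD
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    v <- a * seq_len(sample(3:12, 1)) + b
    expect_equal(csd_profile(v), rep(0, length(v) - 2))
  }
})

test_that("CSD matrix equals brute-force per-event profiles", {
  set.seed(2)
  rec <- lfp_recording(matrix(rnorm(6 * 500), nrow = 6), fs = 1000)
  catalog <- tibble::tibble(peak_sample = c(50L, 200L, 437L))
  M <- csd_matrix(rec, catalog)
  expect_equal(dim(M), c(3, 4))
  for (i in seq_len(3)) {
    expect_equal(M[i, ],
                 csd_profile(rec$samples[, catalog$peak_sample[i]]))
  }
  # 3-channel probe gives a single interior column
  rec3 <- lfp_recording(matrix(rnorm(3 * 100), nrow = 3), fs = 1000)
  expect_equal(ncol(csd_matrix(rec3, tibble::tibble(peak_sample = 10L))), 1)
  expect_error(csd_matrix(lfp_recording(rnorm(100), 1000),
                          tibble::tibble(peak_sample = 10L)), "3 channels")
  expect_error(csd_matrix(rec, tibble::tibble(peak_sample = 10000L)),
               "range")
})

test_that("PC1 reduction keeps the cluster separation and reports variance", {
  # rank-1 matrix: PC1 explains everything
  r1 <- outer(rnorm(20), c(1, 2, 3))
  expect_equal(reduce_first_pc(r1)$variance_explained_2pc, 1)
  # two tight clusters separated along one axis: scores split cleanly
  set.seed(3)
  X <- rbind(matrix(rnorm(150, mean = 0), ncol = 3),
             matrix(rnorm(150, mean = 6), ncol = 3))
  red <- reduce_first_pc(X)
  grp <- rep(1:2, each = 50)
  lo <- range(red$scores[grp == 1]); hi <- range(red$scores[grp == 2])
  if (lo[1] > hi[1]) { tmp <- lo; lo <- hi; hi <- tmp }
  expect_lt(lo[2], hi[1])   # disjoint score ranges = bimodal projection
  expect_error(reduce_first_pc(matrix(1, 5, 3)), "zero variance")
})

test_that("1-D GMM separates well-separated score clouds deterministically", {
  set.seed(4)
  scores <- c(rnorm(100, -5), rnorm(100, 5))
  cl <- cluster_gmm_1d(scores, seed = 1)
  agree <- max(mean((cl$cluster == 1) == (scores < 0)),
               mean((cl$cluster == 2) == (scores < 0)))
  expect_gte(agree, 0.99)
  expect_true(all(cl$posterior > 0.5))
  # near-delta clusters give posteriors ~ 1
  tight <- c(rnorm(50, -5, 0.01), rnorm(50, 5, 0.01))
  expect_true(all(cluster_gmm_1d(tight, seed = 1)$posterior > 0.999))
  # same seed, same labels
  expect_identical(cluster_gmm_1d(scores, seed = 7),
                   cluster_gmm_1d(scores, seed = 7))
  expect_error(cluster_gmm_1d(rep(1, 10)), "distinct")
})

test_that("sink-position rule assigns DS1 to the shallower sink", {
  # cluster 1 sink at interior channel 2, cluster 2 at channel 4
  csd_a <- c(0.1, -1, 0.2, 0.3, 1, 0.2)
  csd_b <- c(0.1, 0.2, 0.3, -1, 1, 0.2)
  map <- assign_types_by_sink(csd_a, csd_b)
  expect_equal(map$type_of_cluster, c(1L, 2L))
  expect_equal(map$sink_channel, c(2L, 4L))
  expect_equal(map$flag, "ok")
  # swapped arguments swap the types
  expect_equal(assign_types_by_sink(csd_b, csd_a)$type_of_cluster,
               c(2L, 1L))
  # identical sinks flagged ambiguous but still deterministic
  amb <- assign_types_by_sink(csd_a, csd_a * 2)
  expect_equal(amb$flag, "ambiguous_equal_sinks")
  expect_setequal(amb$type_of_cluster, c(1L, 2L))
  # no sink above the source: fallback to the global minimum, flagged
  nos <- assign_types_by_sink(c(0.5, 0.4, 1, 0.1, -1, 0), csd_b)
  expect_equal(nos$flag, "no_sink_above_source")
  expect_equal(nos$sink_channel[1], 5L)
})

test_that("CSDbC recovers synthetic ground-truth types", {
  fx <- small_two_type_()
  cls <- classify_csdbc(fx$recording, fx$catalog, seed = 1)
  ok <- !is.na(fx$catalog_true_type)
  expect_gte(mean(cls$label[ok] == fx$catalog_true_type[ok]), 0.9)
  expect_true(all(cls$posterior > 0.5))
  expect_gt(attr(cls, "variance_explained_2pc"), 0.85)
  expect_false(attr(cls, "merged_single_type"))
  # sink channels recovered from the configured laminar profiles
  prof <- default_laminar_profiles(8)
  expected <- sort(c(which.min(csd_profile(prof$ds1)),
                     which.min(csd_profile(prof$ds2))))
  expect_equal(sort(attr(cls, "sink_channel")), expected)
})

test_that("CSDbC is invariant to catalog row order and handles empty input", {
  fx <- small_two_type_()
  cls <- classify_csdbc(fx$recording, fx$catalog, seed = 1)
  rev_cat <- fx$catalog[rev(seq_len(nrow(fx$catalog))), ]
  cls_rev <- classify_csdbc(fx$recording, rev_cat, seed = 1)
  expect_equal(cls_rev$label[rev(seq_len(nrow(cls)))], cls$label)
  empty <- classify_csdbc(fx$recording, fx$catalog[0, ], seed = 1)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "ds_classification")
})
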