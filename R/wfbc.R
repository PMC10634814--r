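#' Parameters of the waveform-based classifier
#'
#' Defaults follow the single-channel classification recipe: 31-sample
#' feature windows (-15..15 ms at 1 kHz), iterative exclusion of artifact
#' clusters smaller than 5% of the total detected events, DS2 assignment by
#' the lower post-peak (10..50 ms) mean-waveform sum, a dissimilarity-index
#' threshold of 0.06 on the +-10 ms scaled second derivatives, and the
#' width-based 2-of-3 vote (width > 19 ms, start < -9.5 ms, end > 9.5 ms
#' each vote DS1) for merged single-type populations.
#'
#' @param window_ms Feature window in ms relative to the peak.
#' @param artifact_min_fraction Clusters below this fraction of the total
#'   detected events are excluded as putative artifacts.
#' @param postpeak_sum_window_ms Window for the type-assignment sum.
#' @param di_window_ms Window for the dissimilarity index.
#' @param di_threshold Merge threshold on the DI (0.06; 0.07 in borderline
#'   datasets).
#' @param vote_width_ms,vote_start_ms,vote_end_ms Width-vote cut-offs.
#' @param n_seeds Number of GMM seeds for accuracy sweeps.
#' @param max_iterations Hard guard on the artifact-exclusion loop.
#' @return A list of class `wfbc_params`.
#' @export
wfbc_params <- function(window_ms = c(-15, 15), artifact_min_fraction = 0.05,
                        postpeak_sum_window_ms = c(10, 50),
                        di_window_ms = c(-10, 10), di_threshold = 0.06,
                        vote_width_ms = 19, vote_start_ms = -9.5,
                        vote_end_ms = 9.5, n_seeds = 20,
                        max_iterations = 20) {
  stopifnot(window_ms[1] < window_ms[2],
            artifact_min_fraction > 0, artifact_min_fraction < 0.5,
            postpeak_sum_window_ms[1] < postpeak_sum_window_ms[2],
            di_window_ms[1] < di_window_ms[2])
  structure(list(window_ms = window_ms,
                 artifact_min_fraction = artifact_min_fraction,
                 postpeak_sum_window_ms = postpeak_sum_window_ms,
                 di_window_ms = di_window_ms, di_threshold = di_threshold,
                 vote_width_ms = vote_width_ms, vote_start_ms = vote_start_ms,
                 vote_end_ms = vote_end_ms, n_seeds = n_seeds,
                 max_iterations = max_iterations),
            class = "wfbc_params")
}

#' Extract the 31-sample feature windows
#'
#' Each event is represented by the raw-LFP amplitudes in a -15..15 ms
#' window around its peak (31 samples at 1 kHz), the feature set of the
#' waveform-based classifier.
#'
#' @inheritParams extract_waveforms
#' @param window_ms Feature window (default -15..15 ms).
#' @return Events x samples matrix; see [extract_waveforms()].
#' @export
extract_feature_windows <- function(x, peaks, window_ms = c(-15, 15),
                                    fs = 1000) {
  extract_waveforms(x, peaks, window_ms = window_ms, fs = fs)
}

# Subset rows of a waveform matrix, preserving its time-base attributes.
subset_waveforms_ <- function(W, idx) {
  out <- W[idx, , drop = FALSE]
  attr(out, "t_ms") <- attr(W, "t_ms")
  attr(out, "fs") <- attr(W, "fs")
  out
}

#' GMM clustering with iterative artifact-cluster exclusion
#'
#' Fits a two-component Gaussian mixture to the feature rows. If one
#' cluster holds fewer than `artifact_min_fraction` (5%) of the *total*
#' detected events it is marked as a putative artifact group and excluded,
#' and clustering is repeated on the remainder, until both clusters hold
#' between 5% and 95% of the total.
#'
#' @param features Events x features matrix (rows are 31-sample waveforms).
#' @param params A [wfbc_params()].
#' @param seed RNG seed for the GMM initialization.
#' @return A list: `cluster` (character `"A"`/`"B"`/`"excluded"` per row,
#'   A the cluster with the larger mean peak amplitude), `posterior`
#'   (assigned-cluster probability, NA for excluded rows) and
#'   `n_iterations`.
#' @export
cluster_waveforms <- function(features, params = wfbc_params(), seed = 1) {
  n_total <- nrow(features)
  if (n_total < 2) stop_("need at least 2 events to cluster")
  if (n_total < 500) {
    warn_("fewer than 500 events (", n_total,
          "); waveform-based classification may be unreliable")
  }
  active <- rep(TRUE, n_total)
  cluster <- rep(NA_integer_, n_total)
  posterior <- rep(NA_real_, n_total)
  for (iter in seq_len(params$max_iterations)) {
    fit <- fit_gmm_(features[active, , drop = FALSE], seed)
    cls <- fit$classification
    frac <- tabulate(cls, 2) / n_total
    if (min(frac) >= params$artifact_min_fraction) {
      cluster[active] <- cls
      posterior[active] <- apply(fit$z, 1, max)
      # canonical labels: A = cluster with the larger mean central value
      centre <- ceiling(ncol(features) / 2)
      m1 <- mean(features[active, , drop = FALSE][cls == 1, centre])
      m2 <- mean(features[active, , drop = FALSE][cls == 2, centre])
      lab <- rep("excluded", n_total)
      first_is_a <- m1 >= m2
      lab[which(active)[cls == 1]] <- if (first_is_a) "A" else "B"
      lab[which(active)[cls == 2]] <- if (first_is_a) "B" else "A"
      return(list(cluster = lab, posterior = posterior,
                  n_iterations = iter))
    }
    minor <- which.min(frac)
    active[which(active)[cls == minor]] <- FALSE
    if (sum(active) < 2) stop_("artifact exclusion removed nearly all events")
  }
  stop_("artifact-exclusion loop failed to terminate in ",
        params$max_iterations, " iterations")
}

#' Assign DS types to the two clusters by the post-peak sum
#'
#' DS2 shows a pronounced negative deflection after the peak, so the
#' cluster whose mean waveform has the *lower* sum over 10..50 ms after the
#' peak is DS2; the other is DS1. An exact tie is flagged and broken toward
#' the cluster with the lower minimum in the window.
#'
#' @param mw_a,mw_b `mean_waveform`s of the two clusters covering the
#'   post-peak window.
#' @param window_ms Post-peak summation window.
#' @return A list with `type_of` (named integer: types of clusters A and
#'   B) and `tie` flag.
#' @export
assign_types_by_postpeak <- function(mw_a, mw_b, window_ms = c(10, 50)) {
  postpeak_sum <- function(mw) {
    sel <- mw$t_ms >= window_ms[1] & mw$t_ms <= window_ms[2]
    if (!any(sel)) stop_("mean waveform does not cover the post-peak window")
    sum(mw$amplitude[sel])
  }
  sa <- postpeak_sum(mw_a)
  sb <- postpeak_sum(mw_b)
  tie <- isTRUE(all.equal(sa, sb))
  if (tie) {
    sel <- function(mw) min(mw$amplitude[mw$t_ms >= window_ms[1] &
                                           mw$t_ms <= window_ms[2]])
    a_is_2 <- sel(mw_a) <= sel(mw_b)
  } else {
    a_is_2 <- sa < sb
  }
  list(type_of = if (a_is_2) c(A = 2L, B = 1L) else c(A = 1L, B = 2L),
       tie = tie)
}

#' Dissimilarity index between two mean waveforms
#'
#' Mean absolute difference between the min-max-scaled (to `[0, 1]`)
#' second derivatives of two mean waveforms within a 20-ms window centred
#' at the peak. DI at or below the threshold (0.06 by default) indicates
#' the two groups are the same DS type.
#'
#' @param mw_a,mw_b `mean_waveform`s on the same time base covering the
#'   window.
#' @param window_ms Comparison window (also the min-max scaling span).
#' @return DI in `[0, 1]`.
#' @export
dissimilarity_index <- function(mw_a, mw_b, window_ms = c(-10, 10)) {
  scaled_d2 <- function(mw) {
    d2 <- second_derivative(mw)
    sel <- d2$t_ms >= window_ms[1] & d2$t_ms <= window_ms[2]
    if (!any(sel)) stop_("waveform does not cover the DI window")
    v <- d2$amplitude[sel]
    rng <- range(v)
    if (diff(rng) == 0) stop_("flat second derivative: DI scaling degenerate")
    (v - rng[1]) / diff(rng)
  }
  a <- scaled_d2(mw_a)
  b <- scaled_d2(mw_b)
  if (length(a) != length(b)) stop_("waveform time bases differ")
  mean(abs(a - b))
}

#' Width-based vote for a merged single-type population
#'
#' Three independent votes from the width measurement of the pooled mean
#' waveform: DS1 is voted if the width exceeds 19 ms, if the start limit
#' precedes -9.5 ms, or if the end limit follows 9.5 ms; otherwise each
#' vote goes to DS2. The type with at least two of three votes wins.
#'
#' @param width A one-row tibble from [measure_width()].
#' @param params A [wfbc_params()] providing the cut-offs.
#' @return A list with `voted_type` (1 or 2) and the logical `votes`
#'   (TRUE = DS1) named width/start/end.
#' @export
vote_single_type <- function(width, params = wfbc_params()) {
  votes <- c(width = width$width_ms > params$vote_width_ms,
             start = width$start_ms < params$vote_start_ms,
             end = width$end_ms > params$vote_end_ms)
  list(voted_type = if (sum(votes) >= 2) 1L else 2L, votes = votes)
}

# Shared single-type check: DI between the two groups' mean waveforms;
# when merged, the pooled mean waveform's width decides the type.
single_type_check_ <- function(W, labels, di_threshold = 0.06,
                               params = wfbc_params()) {
  fs <- attr(W, "fs") %||% 1000
  groups <- sort(unique(labels))
  mws <- lapply(groups, function(g) {
    mean_waveform(subset_waveforms_(W, labels == g), fs = fs)
  })
  di <- dissimilarity_index(mws[[1]], mws[[2]], params$di_window_ms)
  if (di <= di_threshold) {
    pooled <- mean_waveform(W, fs = fs)
    wd <- measure_width(pooled)
    vote <- vote_single_type(wd, params)
    list(di = di, is_single_type = TRUE, voted_type = vote$voted_type,
         votes = vote$votes, width = wd)
  } else {
    list(di = di, is_single_type = FALSE, voted_type = NA_integer_,
         votes = NULL, width = NULL)
  }
}

# Core WFbC on a pre-extracted wide waveform matrix (events x time,
# spanning at least the feature, post-peak and DI windows).
wfbc_core_ <- function(W, params, seed, check_single_type) {
  t_ms <- attr(W, "t_ms")
  fs <- attr(W, "fs") %||% 1000
  feat <- t_ms >= params$window_ms[1] & t_ms <= params$window_ms[2]
  cl <- cluster_waveforms(W[, feat, drop = FALSE], params, seed)
  excluded <- cl$cluster == "excluded"
  mw <- lapply(c("A", "B"), function(g) {
    mean_waveform(subset_waveforms_(W, cl$cluster == g), fs = fs)
  })
  map <- assign_types_by_postpeak(mw[[1]], mw[[2]],
                                  params$postpeak_sum_window_ms)
  labels <- rep(NA_integer_, nrow(W))
  labels[!excluded] <- map$type_of[cl$cluster[!excluded]]
  merged <- FALSE
  di <- NA_real_
  voted <- NA_integer_
  votes <- NULL
  if (check_single_type) {
    stc <- single_type_check_(subset_waveforms_(W, !excluded),
                              labels[!excluded],
                              di_threshold = params$di_threshold,
                              params = params)
    di <- stc$di
    if (stc$is_single_type) {
      merged <- TRUE
      voted <- stc$voted_type
      votes <- stc$votes
      labels[!excluded] <- voted
    }
  }
  list(labels = labels, excluded = excluded, posterior = cl$posterior,
       n_iterations = cl$n_iterations, di = di,
       merged_single_type = merged, voted_type = voted, votes = votes,
       postpeak_tie = map$tie)
}

#' Classify dentate spikes from a single channel (WFbC)
#'
#' The waveform-based classifier: 31-sample peri-peak windows are clustered
#' by a two-component Gaussian mixture with iterative artifact-cluster
#' exclusion; the cluster with the lower post-peak (10..50 ms) sum of its
#' mean waveform is DS2; and an optional dissimilarity-index check merges
#' the clusters into a single type (then typed by the width vote) when
#' their second-derivative dynamics are indistinguishable. Unlike the CSD
#' classifier this needs only one recording channel.
#'
#' @param x Numeric signal (raw LFP, 1 kHz) or an [lfp_recording()].
#' @param catalog Event catalog from [detect_dentate_spikes()]; events
#'   whose +-200 ms waveform window crosses a signal edge are dropped from
#'   the output with a warning.
#' @param channel Channel index or id when `x` is multichannel.
#' @param params A [wfbc_params()].
#' @param seed RNG seed for the GMM; the same seed yields identical labels.
#' @param check_single_type Run the dissimilarity-index merge check.
#' @return A `ds_classification` tibble: `peak_sample`, `label` (1/2, NA
#'   for excluded events), `posterior`, `excluded`; attributes `method`,
#'   `di`, `merged_single_type`, `voted_type`, `votes`, `n_iterations`.
#' @examples
#' out <- synthesize_recording(synth_config(duration_s = 600,
#'                                          n_events = c(150, 150)))
#' cat <- detect_dentate_spikes(out$recording, out$target_channel,
#'                              out$reference_channel)
#' cls <- classify_wfbc(out$recording, cat, channel = out$target_channel)
#' glance(cls)
#' @export
classify_wfbc <- function(x, catalog, channel = NULL,
                          params = wfbc_params(), seed = 1,
                          check_single_type = TRUE) {
  if (inherits(x, "lfp_recording")) {
    if (is.null(channel) && n_channels_(x) > 1) {
      stop_("`channel` required for multichannel recordings")
    }
    signal <- channel_signal_(x, channel %||% 1)
    fs <- x$fs
  } else {
    signal <- x
    fs <- 1000
  }
  if (fs != 1000) stop_("WFbC expects the canonical 1 kHz rate")
  if (nrow(catalog) == 0) {
    return(new_ds_classification_(
      tibble(peak_sample = integer(0), label = integer(0),
             posterior = numeric(0), excluded = logical(0)),
      method = "WFbC", merged_single_type = FALSE, di = NA_real_
    ))
  }
  # canonical event order (by peak time) so results are invariant to the
  # row order of the catalog
  peaks <- sort(catalog$peak_sample)
  W <- extract_waveforms(signal, peaks, window_ms = c(-200, 200), fs = fs)
  core <- wfbc_core_(W, params, seed, check_single_type)
  new_ds_classification_(
    tibble(peak_sample = attr(W, "peak_sample"),
           label = core$labels,
           posterior = core$posterior,
           excluded = core$excluded),
    method = "WFbC",
    merged_single_type = core$merged_single_type, di = core$di,
    voted_type = core$voted_type, votes = core$votes,
    n_iterations = core$n_iterations, postpeak_tie = core$postpeak_tie
  )
}

#' Accuracy of the waveform classifier across feature windows
#'
#' Re-runs the classifier for each candidate feature window and several GMM
#' seeds, reporting the mean and sd of the agreement with a reference
#' labeling (from the CSD classifier or ground truth). Used to verify that
#' the default -15..15 ms window is (near-)optimal on a given dataset.
#'
#' @param x Signal or [lfp_recording()] (see [classify_wfbc()]).
#' @param catalog Event catalog.
#' @param reference_labels Integer labels (1/2) aligned with the catalog.
#' @param windows List of `c(lo, hi)` windows in ms.
#' @param channel,params,check_single_type Passed through.
#' @param n_seeds Number of GMM seeds per window.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @return A tibble: `window_lo_ms`, `window_hi_ms`, `mean_accuracy`,
#'   `sd_accuracy`, `n_runs`.
#' @export
window_size_sweep <- function(x, catalog, reference_labels, windows,
                              channel = NULL, params = wfbc_params(),
                              n_seeds = 20, seed = 1,
                              check_single_type = TRUE) {
  if (length(windows) == 0) stop_("empty window list")
  if (inherits(x, "lfp_recording")) {
    signal <- channel_signal_(x, channel %||% 1)
    fs <- x$fs
  } else {
    signal <- x
    fs <- 1000
  }
  W <- extract_waveforms(signal, catalog$peak_sample,
                         window_ms = c(-200, 200), fs = fs)
  ref <- reference_labels[attr(W, "kept")]
  purrr::map_dfr(windows, function(win) {
    p <- params
    p$window_ms <- win
    accs <- vapply(seq_len(n_seeds), function(i) {
      core <- wfbc_core_(W, p, seed + i - 1, check_single_type)
      ok <- !core$excluded & !is.na(ref)
      mean(core$labels[ok] == ref[ok])
    }, numeric(1))
    tibble(window_lo_ms = win[1], window_hi_ms = win[2],
           mean_accuracy = mean(accs), sd_accuracy = sd(accs),
           n_runs = n_seeds)
  })
}

#' Subsampling experiment: accuracy vs event count and type balance
#'
#' Repeatedly draws random event subsets at given totals and DS2
#' proportions, classifies each subset with the waveform classifier, and
#' summarizes the accuracy against the true labels (median and IQR over
#' rounds) together with the fraction of rounds in which the classifier
#' merged the clusters into a single type. Reproduces the finding that
#' accuracy improves with the number of events and that small samples are
#' increasingly collapsed into one cluster, motivating the > 500-event
#' recommendation.
#'
#' @param W Waveform matrix (events x time) from [extract_waveforms()]
#'   with a -200..200 ms span.
#' @param true_labels Integer labels (1/2) aligned with the rows of `W`.
#' @param totals Total event counts to test.
#' @param ds2_proportions DS2 proportions to test.
#' @param n_rounds Random subsets per condition.
#' @param params A [wfbc_params()].
#' @param seed Base RNG seed.
#' @return A tibble: `total`, `ds2_proportion`, `median_accuracy`,
#'   `iqr_accuracy`, `merged_fraction`, `n_rounds`.
#' @export
subsample_experiment <- function(W, true_labels,
                                 totals = c(200, 500, 1000),
                                 ds2_proportions = 0.5, n_rounds = 200,
                                 params = wfbc_params(), seed = 1) {
  stopifnot(nrow(W) == length(true_labels))
  idx1 <- which(true_labels == 1)
  idx2 <- which(true_labels == 2)
  grid <- tidyr::expand_grid(total = totals, ds2_proportion = ds2_proportions)
  round_seeds <- with_seed_(seed, {
    matrix(sample.int(.Machine$integer.max - 1, nrow(grid) * n_rounds),
           nrow = n_rounds)
  })
  purrr::pmap_dfr(grid, function(total, ds2_proportion) {
    gi <- which(grid$total == total & grid$ds2_proportion == ds2_proportion)
    n2 <- round(total * ds2_proportion)
    n1 <- total - n2
    if (n1 > length(idx1) || n2 > length(idx2)) {
      stop_("insufficient events for total ", total, " at DS2 proportion ",
            ds2_proportion)
    }
    acc <- numeric(n_rounds)
    merged <- logical(n_rounds)
    for (r in seq_len(n_rounds)) {
      rs <- round_seeds[r, gi]
      pick <- with_seed_(rs, c(sample(idx1, n1), sample(idx2, n2)))
      sub <- subset_waveforms_(W, pick)
      core <- suppressWarnings(wfbc_core_(sub, params, rs,
                                          check_single_type = TRUE))
      ok <- !core$excluded
      acc[r] <- mean(core$labels[ok] == true_labels[pick][ok])
      merged[r] <- core$merged_single_type
    }
    tibble(total = total, ds2_proportion = ds2_proportion,
           median_accuracy = median(acc),
           iqr_accuracy = stats::IQR(acc),
           merged_fraction = mean(merged), n_rounds = n_rounds)
  })
}
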