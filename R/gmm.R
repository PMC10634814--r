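# Two-component Gaussian mixture: EM (mclust::me) started from a seeded
# k-means partition of the raw feature rows, as is conventional for
# waveform clustering (k-means anchors the split on the dominant raw-space
# variance direction -- event amplitude -- and EM refines it; this also
# makes labels highly reproducible across seeds). A fallback chain of
# covariance parameterizations guards against singular fits on
# high-dimensional or near-degenerate input.
fit_gmm_ <- function(X, seed, models = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop_("need at least 2 observations for GMM clustering")
  univariate <- ncol(X) == 1
  if (is.null(models)) {
    models <- if (univariate) c("V", "E") else c("VVV", "EEE", "VVI", "EII")
  }
  data <- if (univariate) as.vector(X) else X
  with_seed_(seed, {
    km <- kmeans_pp_(X, k = 2, n_start = 5)
    z0 <- mclust::unmap(km$cluster, groups = 1:2)
    for (m in models) {
      # mclust::me() resolves its `me<MODEL>` worker in the caller frame;
      # fetch the worker from the namespace instead
      worker <- get(paste0("me", m), envir = asNamespace("mclust"))
      fit <- tryCatch(
        suppressWarnings(worker(data = data, z = z0)),
        error = function(e) NULL
      )
      if (is.null(fit) || is.null(fit$z) || anyNA(fit$z) ||
          !is.finite(fit$loglik)) {
        next
      }
      cls <- apply(fit$z, 1, which.max)
      if (length(unique(cls)) == 2) {
        fit$classification <- cls
        return(fit)
      }
    }
    stop_("two-component GMM failed to converge for all covariance models")
  })
}

# k-means with k-means++ seeding (second seed drawn with probability
# proportional to squared distance from the first), best of `n_start`
# runs by within-cluster sum of squares. ++ seeding matters here: a small
# distant artifact group is then almost surely seeded and isolated,
# whereas random-row seeding usually misses it.
kmeans_pp_ <- function(X, k = 2, n_start = 5) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(n_start)) {
    centers <- X[sample.int(n, 1), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(centers, 1, function(cc) {
        rowSums(sweep(X, 2, cc)^2)
      })
      d2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      if (sum(d2) == 0) {
        centers <- rbind(centers, X[sample.int(n, 1), , drop = FALSE])
      } else {
        centers <- rbind(centers, X[sample.int(n, 1, prob = d2), ,
                                    drop = FALSE])
      }
    }
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 50)),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) stop_("k-means failed to initialize")
  best
}
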