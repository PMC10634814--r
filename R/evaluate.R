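#' Agreement between two labelings
#'
#' Fraction of events labeled identically (e.g. by the waveform and the
#' CSD classifiers, or by a classifier and ground truth).
#'
#' @param reference,predicted Equal-length label vectors in the same event
#'   order.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop_("labelings differ in length (", length(reference), " vs ",
          length(predicted), ")")
  }
  if (length(reference) == 0) return(NA_real_)
  mean(reference == predicted)
}

#' Precision and recall for one DS type
#'
#' Precision: fraction of events classified as `type` that truly are that
#' type. Recall: fraction of the events that should have been classified
#' as `type` that were. Undefined denominators are returned as `NA` with
#' an explicit flag, never silently as zero.
#'
#' @param reference,predicted Label vectors (1/2).
#' @param type The DS type evaluated (1 or 2).
#' @return A one-row tibble: `type`, `precision`, `recall`,
#'   `precision_defined`, `recall_defined`.
#' @export
precision_recall <- function(reference, predicted, type) {
  stopifnot(type %in% c(1, 2))
  pred_pos <- predicted == type
  ref_pos <- reference == type
  tp <- sum(pred_pos & ref_pos)
  precision <- if (sum(pred_pos) == 0) NA_real_ else tp / sum(pred_pos)
  recall <- if (sum(ref_pos) == 0) NA_real_ else tp / sum(ref_pos)
  tibble(type = as.integer(type), precision = precision, recall = recall,
         precision_defined = sum(pred_pos) > 0,
         recall_defined = sum(ref_pos) > 0)
}

#' Row-normalized confusion matrix
#'
#' Rows are reference types, columns predicted types, entries row-
#' normalized counts; the main diagonal holds the recalls. A reference
#' type with no events yields an `NA` row.
#'
#' @param reference,predicted Label vectors (1/2).
#' @return A 2 x 2 numeric matrix with dimnames `reference`/`predicted`.
#' @export
confusion_normalized <- function(reference, predicted) {
  m <- matrix(NA_real_, 2, 2,
              dimnames = list(reference = c("DS1", "DS2"),
                              predicted = c("DS1", "DS2")))
  for (r in 1:2) {
    sel <- reference == r
    if (any(sel)) {
      m[r, ] <- c(mean(predicted[sel] == 1), mean(predicted[sel] == 2))
    }
  }
  m
}

#' Agreement between per-channel metric values from two methods
#'
#' Pearson correlation, least-squares slope, and the Wald t-test of the
#' regression slope against 1 (a slope indistinguishable from 1 with high
#' correlation indicates the two methods measure the same quantity on the
#' same scale).
#'
#' @param values_method1,values_method2 Paired numeric vectors (>= 3
#'   pairs).
#' @return A one-row tibble: `pearson_r`, `slope`, `slope_vs_1_p`, `n`.
#' @export
metric_agreement <- function(values_method1, values_method2) {
  x <- values_method1
  y <- values_method2
  if (length(x) != length(y)) stop_("paired values differ in length")
  if (length(x) < 3) stop_("need at least 3 paired values")
  if (var(x) == 0 || var(y) == 0) stop_("zero variance in one series")
  fit <- lm(y ~ x)
  est <- suppressWarnings(summary(fit))$coefficients
  slope <- est["x", "Estimate"]
  se <- est["x", "Std. Error"]
  if (abs(slope - 1) < 1e-10) {
    p <- 1   # exact identity: rounding noise in se would corrupt the ratio
  } else {
    tval <- (slope - 1) / se
    p <- 2 * pt(-abs(tval), df = fit$df.residual)
  }
  tibble(pearson_r = stats::cor(x, y), slope = slope, slope_vs_1_p = p,
         n = length(x))
}

#' Compare two DS classifications of the same events
#'
#' Aligns two `ds_classification` objects (or plain label tibbles) on
#' `peak_sample`, drops events excluded (artifact-flagged) by either
#' method, and reports accuracy, per-type precision/recall, and the
#' row-normalized confusion matrix with the first argument as reference.
#'
#' @param reference,predicted `ds_classification` tibbles (or tibbles with
#'   `peak_sample` and `label`).
#' @return An `evaluation_report` list: `n_events`, `n_dropped`,
#'   `accuracy`, `per_type` (tibble from [precision_recall()]),
#'   `confusion` (2 x 2 matrix).
#' @export
evaluate_classifications <- function(reference, predicted) {
  merged <- dplyr::inner_join(
    tibble(peak_sample = reference$peak_sample, ref = reference$label,
           ref_excl = reference$excluded %||% FALSE),
    tibble(peak_sample = predicted$peak_sample, pred = predicted$label,
           pred_excl = predicted$excluded %||% FALSE),
    by = "peak_sample"
  )
  n_all <- nrow(merged)
  keep <- !merged$ref_excl & !merged$pred_excl &
    !is.na(merged$ref) & !is.na(merged$pred)
  merged <- merged[keep, ]
  structure(
    list(
      n_events = nrow(merged),
      n_dropped = n_all - nrow(merged),
      accuracy = accuracy(merged$ref, merged$pred),
      per_type = dplyr::bind_rows(
        precision_recall(merged$ref, merged$pred, 1),
        precision_recall(merged$ref, merged$pred, 2)
      ),
      confusion = confusion_normalized(merged$ref, merged$pred)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d events compared (%d dropped), accuracy %.3f\n",
              x$n_events, x$n_dropped, x$accuracy))
  print(x$per_type)
  cat("confusion (rows = reference, diagonal = recall):\n")
  print(round(x$confusion, 3))
  invisible(x)
}
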