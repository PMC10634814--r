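#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a DS classification
#'
#' @param x A `ds_classification`.
#' @param ... Unused.
#' @return A plain tibble with `peak_sample`, `label`, `posterior`,
#'   `excluded` and a `method` column.
#' @export
tidy.ds_classification <- function(x, ...) {
  out <- as_tibble(unclass_tbl_(x))
  out$method <- attr(x, "method") %||% NA_character_
  out
}

#' One-row summary of a DS classification
#'
#' @param x A `ds_classification`.
#' @param ... Unused.
#' @return A one-row tibble: event counts per type, excluded count, the
#'   dissimilarity index, the merge flag and the method tag.
#' @export
glance.ds_classification <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_events = nrow(x),
    n_ds1 = sum(x$label == 1, na.rm = TRUE),
    n_ds2 = sum(x$label == 2, na.rm = TRUE),
    n_excluded = sum(x$excluded),
    di = attr(x, "di") %||% NA_real_,
    merged_single_type = isTRUE(attr(x, "merged_single_type")),
    n_iterations = attr(x, "n_iterations") %||% NA_integer_
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report` from [evaluate_classifications()].
#' @param ... Unused.
#' @return The per-type precision/recall tibble.
#' @export
tidy.evaluation_report <- function(x, ...) x$per_type

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A one-row tibble with `n_events`, `n_dropped`, `accuracy`.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(n_events = x$n_events, n_dropped = x$n_dropped,
         accuracy = x$accuracy)
}

unclass_tbl_ <- function(x) {
  class(x) <- setdiff(class(x), c("ds_classification", "delta_states"))
  for (nm in setdiff(names(attributes(x)),
                     c("names", "row.names", "class"))) {
    attr(x, nm) <- NULL
  }
  x
}
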