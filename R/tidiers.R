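# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model matrix into its triage table
#'
#' @param x a `qsar_model_matrix`.
#' @param ... passed to [triage()].
#' @return a tibble, one row per attempted model.
#' @export
tidy.qsar_model_matrix <- function(x, ...) {
  as_tibble(triage(x, ...))
}

#' One-row summary of a model matrix
#'
#' @param x a `qsar_model_matrix`.
#' @param ... unused.
#' @return tibble with attempt/built/failure counts and the best test
#'   statistic.
#' @export
glance.qsar_model_matrix <- function(x, ...) {
  tbl <- triage(x)
  best <- if (x$endpoint_type == "categorical") {
    suppressWarnings(max(tbl$test_roc_auc, na.rm = TRUE))
  } else {
    suppressWarnings(max(tbl$test_r_squared, na.rm = TRUE))
  }
  tibble(
    n_attempted = nrow(tbl),
    n_built = sum(tbl$status == "built"),
    n_failed = sum(tbl$status == "failed"),
    best_test_stat = if (is.finite(best)) best else NA_real_,
    statistic = if (x$endpoint_type == "categorical") "roc_auc" else "r_squared"
  )
}

#' Tidy one model result
#'
#' @param x a `qsar_model_result`.
#' @param set `"test"`, `"train"` or `"both"`.
#' @param ... unused.
#' @return tibble of per-record observations and predictions.
#' @export
tidy.qsar_model_result <- function(x, set = c("both", "test", "train"), ...) {
  set <- match.arg(set)
  assert_that(x$status == "built", "no predictions: model was not built")
  sets <- if (set == "both") c("train", "test") else set
  dplyr::bind_rows(purrr::map(sets, function(s)
    dplyr::mutate(x$predictions[[s]], set = s)))
}

#' One-row summary of a model result
#'
#' @param x a `qsar_model_result`.
#' @param ... unused.
#' @return tibble with the provenance triple, status and statistics.
#' @export
glance.qsar_model_result <- function(x, ...) {
  triage(list(x))
}
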