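# ggplot2 views of the result types: split MDS maps, ROC/REC families,
# and the train-versus-test triage summary plot.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_step
#'   geom_abline labs coord_equal
NULL

#' Plot a split in chemical space
#'
#' MDS map of the fingerprint-similarity space with train and test
#' membership; whole-cluster splits show test "islands".
#'
#' @param object a `split_analysis` from [analyze_split()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.split_analysis <- function(object, ...) {
  ggplot(object$coords, aes(x = .data$x, y = .data$y,
    colour = .data$set, shape = .data$set)) +
    geom_point(alpha = 0.8) +
    coord_equal() +
    labs(title = paste("Split:", object$label),
      subtitle = sprintf("MDS stress %.3f; mean nearest-train similarity %.3f",
        object$stress, object$mean_nn_similarity),
      x = "MDS 1", y = "MDS 2")
}

#' Train-versus-test summary plot of a triage table
#'
#' One point per built model, coloured by learner: test statistic against
#' training statistic (ROC AUC for categorical endpoints, R squared for
#' continuous). Points far below the diagonal indicate over-fitting.
#'
#' @param object a `triage_table`.
#' @param stat base statistic name (default `"roc_auc"` when present,
#'   else `"r_squared"`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.triage_table <- function(object, stat = NULL, ...) {
  stat <- stat %||% (if ("train_roc_auc" %in% names(object)) "roc_auc" else "r_squared")
  xs <- paste0("train_", stat); ys <- paste0("test_", stat)
  assert_that(all(c(xs, ys) %in% names(object)),
    sprintf("statistic %s not present in triage table", stat))
  ggplot(as_tibble(object), aes(x = .data[[xs]], y = .data[[ys]],
    colour = .data$learner_name)) +
    geom_point(alpha = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    labs(x = paste("train", stat), y = paste("test", stat),
      colour = "learner")
}

#' ROC curves of one or more model results
#'
#' @param results a `qsar_model_matrix`, list of results, or single result.
#' @param set `"test"` or `"train"`.
#' @return a ggplot.
#' @export
plot_roc <- function(results, set = c("test", "train")) {
  set <- match.arg(set)
  if (inherits(results, "qsar_model_result")) results <- list(results)
  if (inherits(results, "qsar_model_matrix")) results <- results$results
  field <- paste0(set, "_stats")
  curves <- purrr::imap(results, function(r, i) {
    st <- r[[field]]
    if (is.null(st$roc_points)) return(NULL)
    dplyr::mutate(st$roc_points, model_id = r$model_id,
      learner_name = r$learner_name)
  })
  df <- dplyr::bind_rows(curves)
  assert_that(nrow(df) > 0, "no ROC curves available")
  ggplot(df, aes(x = .data$fpr, y = .data$tpr,
    group = .data$model_id, colour = .data$learner_name)) +
    geom_line(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "false positive rate", y = "true positive rate",
      colour = "learner", title = paste(set, "set ROC"))
}

#' REC curves of one or more model results
#'
#' @inheritParams plot_roc
#' @return a ggplot.
#' @export
plot_rec <- function(results, set = c("test", "train")) {
  set <- match.arg(set)
  if (inherits(results, "qsar_model_result")) results <- list(results)
  if (inherits(results, "qsar_model_matrix")) results <- results$results
  field <- paste0(set, "_stats")
  curves <- purrr::imap(results, function(r, i) {
    st <- r[[field]]
    if (is.null(st$rec_points)) return(NULL)
    dplyr::mutate(st$rec_points, model_id = r$model_id,
      learner_name = r$learner_name)
  })
  df <- dplyr::bind_rows(curves)
  assert_that(nrow(df) > 0, "no REC curves available")
  ggplot(df, aes(x = .data$epsilon, y = .data$fraction,
    group = .data$model_id, colour = .data$learner_name)) +
    geom_line(alpha = 0.6) +
    labs(x = "error tolerance", y = "fraction within tolerance",
      colour = "learner", title = paste(set, "set REC"))
}
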