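# Model validation statistics: confusion rates, ROC/AUC, regression
# statistics, REC curves, the sortable triage table and Y-scrambling.

#' Confusion counts, sensitivity and specificity
#'
#' Binary confusion matrix with the stated positive class. When a class
#' is absent from the truth the affected rate is reported as `NA`, never
#' silently zero.
#'
#' @param labels_true,labels_pred character vectors of binary labels.
#' @param positive_class the positive label.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
confusion_and_rates <- function(labels_true, labels_pred, positive_class) {
  assert_that(length(labels_true) == length(labels_pred),
    "label vectors differ in length")
  pos_t <- labels_true == positive_class
  pos_p <- labels_pred == positive_class
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p); fp <- sum(!pos_t & pos_p)
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' ROC curve and area under it
#'
#' Threshold sweep over the distinct scores in descending order, with
#' tied scores grouped into a single step; area by the trapezoidal rule.
#' Equivalent to pairwise concordance with ties counted one half.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels binary labels.
#' @param positive_class the positive label.
#' @return list with `points` (tibble `fpr`, `tpr`, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  assert_that(n_pos > 0 && n_neg > 0,
    "ROC requires both classes to be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into one step
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(p, grp, sum)
  fp_steps <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / n_pos)
  fpr <- c(0, cumsum(fp_steps) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = tibble(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
    auc = as.numeric(auc))
}

#' Regression statistics
#'
#' Coefficient of determination `1 - SSres/SStot` (against the truth
#' mean) and root mean squared error. With zero variance in the truth,
#' `r_squared` is `NA` and `rmse` is still returned.
#'
#' @param y_true,y_pred numeric vectors.
#' @return list with `r_squared` and `rmse`.
#' @export
regression_stats <- function(y_true, y_pred) {
  assert_that(length(y_true) >= 2, "need at least 2 observations")
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  list(
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean((y_true - y_pred)^2))
  )
}

#' Regression error characteristic (REC) curve
#'
#' For each error tolerance epsilon, the fraction of records predicted
#' within `|error| <= epsilon`. The area is computed over the grid span
#' and normalised to [0, 1] so models on different response scales are
#' comparable. Default grid: 100 evenly spaced tolerances from 0 to the
#' maximum absolute error.
#'
#' @param y_true,y_pred numeric vectors.
#' @param epsilon_grid increasing non-negative tolerances (optional).
#' @return list with `points` (tibble `epsilon`, `fraction`) and `area`.
#' @export
rec_curve <- function(y_true, y_pred, epsilon_grid = NULL) {
  err <- abs(y_true - y_pred)
  if (is.null(epsilon_grid)) {
    epsilon_grid <- seq(0, max(err), length.out = 100)
  }
  assert_that(length(epsilon_grid) > 0, "epsilon grid must be non-empty")
  frac <- vapply(epsilon_grid, function(e) mean(err <= e), numeric(1))
  span <- max(epsilon_grid) - min(epsilon_grid)
  area <- if (span > 0) {
    sum(diff(epsilon_grid) *
      (utils::head(frac, -1) + utils::tail(frac, -1)) / 2) / span
  } else {
    mean(frac)
  }
  list(points = tibble(epsilon = epsilon_grid, fraction = frac), area = area)
}

# Full ValidationStats for one prediction set.
validation_stats <- function(y_true, pred, score = NULL,
                             endpoint_type, positive_class = NULL) {
  if (endpoint_type == "categorical") {
    cm <- confusion_and_rates(y_true, pred, positive_class)
    roc <- tryCatch(roc_auc(score, y_true, positive_class),
      error = function(e) NULL)
    c(cm, list(
      roc_auc = if (is.null(roc)) NA_real_ else roc$auc,
      roc_points = if (is.null(roc)) NULL else roc$points,
      accuracy = mean(y_true == pred)
    ))
  } else {
    rs <- regression_stats(y_true, pred)
    rec <- rec_curve(y_true, pred)
    c(rs, list(rec_area = rec$area, rec_points = rec$points))
  }
}

# ---- triage --------------------------------------------------------------

stats_row <- function(st, prefix) {
  if (is.null(st)) return(tibble(.rows = 1))
  keep <- c("sensitivity", "specificity", "roc_auc", "accuracy",
    "r_squared", "rmse", "rec_area", "tp", "fp", "tn", "fn")
  vals <- st[intersect(keep, names(st))]
  if (!length(vals)) return(tibble(.rows = 1))
  names(vals) <- paste0(prefix, "_", names(vals))
  as_tibble(vals)
}

#' Triage table over a model matrix
#'
#' Flattens a collection of model results into one sortable, filterable
#' row per model carrying the provenance triple (split, subset, learner)
#' and all train/test statistics — the spreadsheet view used to compare
#' and select models. Filtering and sorting never mutate the underlying
#' results. The same table drives the train-versus-test summary plot.
#'
#' @param results a `qsar_model_matrix` or list of model results.
#' @param sort_keys character vector of column names to sort by.
#' @param descending sort direction, recycled over `sort_keys`.
#' @param filters optional expressions (as one-sided formulas or quosures
#'   are not needed; pass expressions via `...` of [dplyr::filter()] on
#'   the returned table for ad hoc work) — here a named list of
#'   `function(tbl) logical` predicates.
#' @return a `triage_table` tibble.
#' @export
triage <- function(results, sort_keys = NULL, descending = TRUE,
                   filters = NULL) {
  if (inherits(results, "qsar_model_matrix")) results <- results$results
  assert_that(length(results) > 0, "no model results to triage")
  rows <- purrr::map(results, function(r) {
    dplyr::bind_cols(
      tibble(
        model_id = r$model_id, split_label = r$split_label,
        subset_label = r$subset_label, learner_name = r$learner_name,
        status = r$status,
        failure_reason = r$failure_reason %||% NA_character_
      ),
      stats_row(r$train_stats, "train"),
      stats_row(r$test_stats, "test")
    )
  })
  tbl <- dplyr::bind_rows(rows)
  if (!is.null(filters)) {
    for (f in filters) tbl <- tbl[which(f(tbl)), , drop = FALSE]
  }
  if (!is.null(sort_keys)) {
    unknown <- setdiff(sort_keys, names(tbl))
    assert_that(length(unknown) == 0,
      sprintf("unknown sort key(s): %s", paste(unknown, collapse = ", ")))
    descending <- rep_len(descending, length(sort_keys))
    ords <- purrr::map2(sort_keys, descending, function(k, d) {
      v <- tbl[[k]]
      if (d && is.numeric(v)) -xtfrm(v) else xtfrm(v)
    })
    tbl <- tbl[do.call(order, ords), , drop = FALSE]  # order() is stable
  }
  class(tbl) <- c("triage_table", class(tbl))
  tbl
}

#' Breakdown counts for a model selection
#'
#' Counts a (filtered) triage selection by learner, split or subset — the
#' view behind statements like "of the selected models, 28 were built
#' with the neural network". Counts always sum to the selection size.
#'
#' @param table a `triage_table` (possibly filtered).
#' @param by `"learner_name"`, `"split_label"` or `"subset_label"`.
#' @return tibble of `by` value and `n`.
#' @export
triage_breakdown <- function(table, by = c("learner_name", "split_label",
                                           "subset_label")) {
  by <- match.arg(by)
  dplyr::count(as_tibble(table), .data[[by]], name = "n")
}

# ---- Y-scrambling --------------------------------------------------------

#' Y-scrambling validation
#'
#' Estimates the chance-correlation baseline of one model configuration:
#' the training-set responses are permuted, the model refit and the test
#' statistic (ROC AUC or R squared) recorded, `n_permutations` times.
#' A real structure-activity signal shows as the observed statistic
#' exceeding the scrambled distribution.
#'
#' @param dataset a prepared `qsar_dataset`.
#' @param descriptors a `descriptor_set` covering the dataset.
#' @param assignment a `split_assignment`.
#' @param subset_blocks character vector of descriptor block names.
#' @param learner learner name.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed.
#' @param params learner parameter overrides.
#' @return list with `observed`, `scrambled` (vector), `scrambled_mean`,
#'   `scrambled_sd`, `exceedance` (fraction of scrambled >= observed)
#'   and `statistic` name.
#' @export
y_scramble <- function(dataset, descriptors, assignment, subset_blocks,
                       learner, n_permutations = 20, seed = 1,
                       params = list()) {
  assert_that(n_permutations >= 1, "n_permutations must be at least 1")
  ep <- endpoint_type(dataset)
  stat_of <- function(ds) {
    res <- train_model_core(ds, descriptors, assignment, subset_blocks,
      learner, params, seed, "yscramble")
    assert_that(res$status == "built",
      paste("model failed:", res$failure_reason))
    if (ep == "categorical") res$test_stats$roc_auc else res$test_stats$r_squared
  }
  observed <- stat_of(dataset)
  meta <- dataset_meta(dataset)
  rec <- as_tibble(dataset)
  in_train <- rec$record_id %in% assignment$train_ids
  scrambled <- vapply(seq_len(n_permutations), function(i) {
    perm_rec <- rec
    withr::with_seed(derive_seed(seed, paste0("perm", i)), {
      perm_rec$response[in_train] <- sample(rec$response[in_train])
    })
    stat_of(with_meta(perm_rec, meta))
  }, numeric(1))
  list(
    observed = observed, scrambled = scrambled,
    scrambled_mean = mean(scrambled), scrambled_sd = stats::sd(scrambled),
    exceedance = mean(scrambled >= observed),
    statistic = if (ep == "categorical") "roc_auc" else "r_squared"
  )
}
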