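# The model matrix: cartesian product of splits x descriptor subsets x
# learners, built cell by cell with failure isolation and incremental,
# resumable persistence. No competitive selection happens here: every
# attempted cell is kept and ranking lives only in the triage views.

#' Enumerate the model matrix
#'
#' Cartesian product of splits, descriptor subsets and learners, filtered
#' to the learners supporting the endpoint type, in deterministic
#' (split, subset, learner) order.
#'
#' @param splits list of `split_assignment`s (or character labels).
#' @param subsets subsets tibble from [make_subsets()].
#' @param learners character vector of learner names.
#' @param endpoint_type `"categorical"` or `"continuous"`.
#' @return tibble with `split_label`, `subset_label`, `learner_name`.
#' @export
enumerate_models <- function(splits, subsets, learners, endpoint_type) {
  assert_that(length(splits) > 0 && nrow(subsets) > 0 && length(learners) > 0,
    "splits, subsets and learners must be non-empty")
  split_labels <- if (is.character(splits)) splits else
    vapply(splits, `[[`, character(1), "label")
  supporting <- intersect(learners, learners_supporting(endpoint_type))
  assert_that(length(supporting) > 0,
    sprintf("no learner supports %s endpoints", endpoint_type))
  tidyr::expand_grid(
    split_label = split_labels,
    subset_label = subsets$label,
    learner_name = supporting
  )
}

dataset_digest <- function(dataset) {
  stable_id(list(dataset$record_id, dataset$smiles_std, dataset$response))
}

# Fit one cell and compute its train/test statistics. Exceptions become
# status = "failed" with the reason recorded; the run continues.
train_model_core <- function(dataset, descriptors, assignment, subset_blocks,
                             learner, params, seed, subset_label,
                             split_label = assignment$label) {
  model_id <- stable_id(list(split_label, subset_label, learner, params,
    dataset_digest(dataset)))
  base <- list(
    model_id = model_id, split_label = split_label,
    subset_label = subset_label, learner_name = learner,
    status = "failed", failure_reason = NULL, fitted_model = NULL,
    train_stats = NULL, test_stats = NULL
  )
  out <- tryCatch({
    ep <- endpoint_type(dataset)
    X <- subset_matrix(descriptors, subset_blocks, dataset$record_id)
    y <- if (ep == "categorical") as.character(dataset$response)
      else as.numeric(dataset$response)
    names(y) <- dataset$record_id
    tr <- assignment$train_ids; te <- assignment$test_ids
    pos <- attr(dataset, "positive_class")
    fit <- fit_learner(learner, X[tr, , drop = FALSE], y[tr], ep,
      positive_class = pos, params = params,
      seed = derive_seed(seed, model_id))
    pos <- fit$positive_class
    pr_tr <- predict_learner(fit, X[tr, , drop = FALSE])
    pr_te <- predict_learner(fit, X[te, , drop = FALSE])
    base$fitted_model <- fit
    base$train_stats <- validation_stats(y[tr], pr_tr$pred, pr_tr$score, ep, pos)
    base$test_stats <- validation_stats(y[te], pr_te$pred, pr_te$score, ep, pos)
    base$predictions <- list(
      train = tibble(record_id = tr, observed = unname(y[tr]),
        predicted = unname(pr_tr$pred),
        score = if (is.null(pr_tr$score)) NA_real_ else unname(pr_tr$score)),
      test = tibble(record_id = te, observed = unname(y[te]),
        predicted = unname(pr_te$pred),
        score = if (is.null(pr_te$score)) NA_real_ else unname(pr_te$score))
    )
    base$status <- "built"
    base
  }, error = function(e) {
    base$failure_reason <- conditionMessage(e)
    base
  })
  structure(out, class = "qsar_model_result")
}

#' @export
print.qsar_model_result <- function(x, ...) {
  cat(sprintf("<qsar_model_result> %s: %s / %s / %s — %s\n",
    x$model_id, x$split_label, x$subset_label, x$learner_name, x$status))
  if (x$status == "failed") cat("reason:", x$failure_reason, "\n")
  invisible(x)
}

#' Train one model-matrix cell
#'
#' Fits the given learner on the training side of the split using the
#' expanded descriptor matrix of the subset, and computes train and test
#' statistics. Any learner exception is captured as a failed result —
#' failures are data, not errors.
#'
#' @param spec one-row tibble (or list) with `split_label`,
#'   `subset_label`, `learner_name`.
#' @param dataset a prepared `qsar_dataset`.
#' @param descriptors a `descriptor_set`.
#' @param assignment the `split_assignment` named by the spec.
#' @param subsets subsets tibble from [make_subsets()].
#' @param params learner parameter overrides.
#' @param seed integer seed (per-model seeds are derived from it).
#' @return a `qsar_model_result`.
#' @export
train_model <- function(spec, dataset, descriptors, assignment, subsets,
                        params = list(), seed = 1) {
  blocks <- subsets$blocks[[match(spec$subset_label, subsets$label)]]
  train_model_core(dataset, descriptors, assignment, blocks,
    spec$learner_name, params, seed, spec$subset_label, spec$split_label)
}

# ---- project -------------------------------------------------------------

#' Create or open a modelling project
#'
#' A project bundles the prepared dataset, splits, descriptors and model
#' results, with a backing directory for incremental result persistence
#' (making interrupted matrix runs resumable).
#'
#' @param path backing directory (created if needed).
#' @return a `qsar_project`.
#' @export
qsar_project <- function(path = tempfile("qsar_project_")) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "models"), showWarnings = FALSE)
  structure(
    list(path = path, dataset = NULL, splits = NULL, descriptors = NULL,
      subsets = NULL, learner_params = list()),
    class = "qsar_project"
  )
}

#' @export
print.qsar_project <- function(x, ...) {
  cat("<qsar_project>", x$path, "\n")
  cat(sprintf(
    "  dataset: %s | splits: %s | descriptors: %s | subsets: %s\n",
    if (is.null(x$dataset)) "-" else nrow(x$dataset),
    if (is.null(x$splits)) "-" else length(x$splits),
    if (is.null(x$descriptors)) "-" else
      paste(names(x$descriptors$blocks), collapse = ","),
    if (is.null(x$subsets)) "-" else nrow(x$subsets)
  ))
  invisible(x)
}

#' Attach prepared data, splits and descriptors to a project
#'
#' @param project a `qsar_project`.
#' @param dataset a prepared `qsar_dataset`.
#' @param splits named list of `split_assignment`s.
#' @param descriptors a `descriptor_set`.
#' @param subsets subsets tibble from [make_subsets()].
#' @return the updated project.
#' @export
project_set_stages <- function(project, dataset = NULL, splits = NULL,
                               descriptors = NULL, subsets = NULL) {
  project$dataset <- dataset %||% project$dataset
  project$splits <- splits %||% project$splits
  project$descriptors <- descriptors %||% project$descriptors
  project$subsets <- subsets %||% project$subsets
  project
}

#' Run the model matrix
#'
#' Attempts every spec, persisting each result incrementally under the
#' project directory; re-running skips already-built model ids, so an
#' interrupted run resumes where it stopped. A failure in one cell never
#' affects another.
#'
#' @param project a `qsar_project` with dataset, splits, descriptors and
#'   subsets attached.
#' @param specs tibble from [enumerate_models()]; default enumerates the
#'   full matrix over all registry learners.
#' @param seed integer seed.
#' @param params named list of per-learner parameter overrides.
#' @param progress print progress every 50 cells.
#' @return a `qsar_model_matrix` (list of results + the spec table).
#' @export
run_matrix <- function(project, specs = NULL, seed = 1, params = list(),
                       progress = FALSE) {
  assert_that(!is.null(project$dataset) && !is.null(project$splits) &&
    !is.null(project$descriptors) && !is.null(project$subsets),
    "project must have dataset, splits, descriptors and subsets attached")
  ep <- endpoint_type(project$dataset)
  specs <- specs %||% enumerate_models(project$splits, project$subsets,
    learner_registry()$name, ep)
  results <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    assignment <- project$splits[[spec$split_label]]
    assert_that(!is.null(assignment),
      sprintf("unknown split label: %s", spec$split_label))
    lp <- params[[spec$learner_name]] %||% list()
    blocks <- project$subsets$blocks[[match(spec$subset_label, project$subsets$label)]]
    model_id <- stable_id(list(spec$split_label, spec$subset_label,
      spec$learner_name, lp, dataset_digest(project$dataset)))
    cache <- file.path(project$path, "models", paste0(model_id, ".rds"))
    if (file.exists(cache)) {
      res <- readRDS(cache)
    } else {
      res <- train_model_core(project$dataset, project$descriptors,
        assignment, blocks, spec$learner_name, lp, seed, spec$subset_label,
        spec$split_label)
      saveRDS(res, cache)
    }
    results[[res$model_id]] <- res
    if (progress && i %% 50 == 0) {
      message(sprintf("  %d / %d models attempted", i, nrow(specs)))
    }
  }
  structure(list(results = results, specs = specs, endpoint_type = ep),
    class = "qsar_model_matrix")
}

#' @export
print.qsar_model_matrix <- function(x, ...) {
  built <- sum(vapply(x$results, function(r) r$status == "built", logical(1)))
  cat(sprintf("<qsar_model_matrix> %d models attempted, %d built, %d failed\n",
    length(x$results), built, length(x$results) - built))
  invisible(x)
}

# ---- protocols -----------------------------------------------------------

.workflow_stages <- c("prep", "split", "descriptors", "build")

#' Save a modelling protocol
#'
#' Captures a contiguous range of the modelling workflow (prep, split,
#' descriptors, build) as a replayable structured-text file, so validated
#' best practice can be redeployed on new datasets of the same kind.
#'
#' @param project a `qsar_project` holding the stages to capture.
#' @param stages contiguous subset of
#'   `c("prep", "split", "descriptors", "build")`.
#' @param path output file (YAML).
#' @param seed seed stored for split regeneration.
#' @return `path`, invisibly.
#' @export
save_protocol <- function(project, stages = .workflow_stages, path, seed = 1) {
  idx <- match(stages, .workflow_stages)
  assert_that(!anyNA(idx) && all(diff(idx) == 1),
    "stages must be a contiguous range of prep, split, descriptors, build")
  proto <- list(endpoint_type = endpoint_type(project$dataset),
    stages = stages, seed = seed)
  if ("prep" %in% stages) {
    proto$prep_spec <- prep_spec(project$dataset)
    proto$positive_class <- attr(project$dataset, "positive_class")
  }
  if ("split" %in% stages) {
    proto$splits <- purrr::map(project$splits, function(s) list(
      label = s$label, algorithm = s$algorithm,
      train_fraction = s$train_fraction, seed = s$seed, params = s$params,
      assignment = if (s$algorithm == "predefined")
        list(train = s$train_ids, test = s$test_ids)
    ))
  }
  if ("descriptors" %in% stages) {
    proto$descriptors <- project$descriptors$provenance
    proto$subsets <- purrr::map(
      stats::setNames(project$subsets$blocks, project$subsets$label), identity)
  }
  if ("build" %in% stages) {
    proto$learners <- learners_supporting(endpoint_type(project$dataset))
    proto$learner_params <- project$learner_params
  }
  yaml::write_yaml(proto, path)
  invisible(path)
}

#' Replay a protocol on a (new) dataset
#'
#' Executes the captured stages on the given raw dataset. The endpoint
#' type is checked before any computation. Splits are regenerated with
#' the stored algorithms and seeds; predefined splits replay their stored
#' assignment and therefore require the same record ids.
#'
#' @param path protocol file from [save_protocol()].
#' @param dataset a raw (unprepared) `qsar_dataset`.
#' @param project_path backing directory for the replayed project.
#' @return a list with the replayed `project` and, when the build stage
#'   is included, the `matrix` of results.
#' @export
replay_protocol <- function(path, dataset, project_path = tempfile("replay_")) {
  proto <- yaml::read_yaml(path)
  assert_that(identical(proto$endpoint_type, endpoint_type(dataset)) ||
      ("prep" %in% proto$stages &&
        any(vapply(proto$prep_spec, function(s) s$name == "categorize", logical(1))) &&
        endpoint_type(dataset) == "continuous") ||
      is.null(proto$endpoint_type),
    sprintf("protocol endpoint type (%s) incompatible with dataset (%s)",
      proto$endpoint_type, endpoint_type(dataset)))
  project <- qsar_project(project_path)
  out <- list()
  if ("prep" %in% proto$stages) {
    dataset <- apply_prep_spec(dataset, proto$prep_spec,
      positive_class = proto$positive_class)
  }
  project$dataset <- dataset
  if ("split" %in% proto$stages) {
    cluster_cache <- list()
    get_clusters <- function(p) {
      key <- paste(p$fingerprint_kind %||% "ECFP6",
        p$similarity_threshold %||% 0.7)
      if (is.null(cluster_cache[[key]])) {
        cluster_cache[[key]] <<- cluster_molecules(dataset,
          fingerprint_kind = p$fingerprint_kind %||% "ECFP6",
          similarity_threshold = p$similarity_threshold %||% 0.7)
      }
      cluster_cache[[key]]
    }
    project$splits <- purrr::map(proto$splits, function(s) {
      switch(s$algorithm,
        random = random_split(dataset, s$train_fraction, s$seed, s$label),
        stratified = stratified_split(dataset, s$train_fraction,
          s$params$n_bins %||% 5, s$seed, s$label),
        independent_clusters_optimized = independent_cluster_split(
          dataset, get_clusters(s$params), s$train_fraction, s$seed, s$label),
        random_per_cluster = random_per_cluster_split(
          dataset, get_clusters(s$params), s$train_fraction, s$seed, s$label),
        predefined = {
          tmp <- tempfile(fileext = ".txt")
          utils::write.table(
            data.frame(
              id = c(s$assignment$train, s$assignment$test),
              set = rep(c("train", "test"),
                c(length(s$assignment$train), length(s$assignment$test)))),
            tmp, row.names = FALSE, col.names = FALSE, quote = FALSE)
          load_predefined_split(dataset, tmp, label = s$label)
        },
        abort(sprintf("unknown split algorithm in protocol: %s", s$algorithm))
      )
    })
    names(project$splits) <- vapply(project$splits, `[[`, character(1), "label")
  }
  if ("descriptors" %in% proto$stages) {
    project$descriptors <- compute_descriptors(dataset,
      blocks = proto$descriptors$blocks,
      fold_width = proto$descriptors$fold_width)
    project$subsets <- make_subsets(proto$subsets)
  }
  out$project <- project
  if ("build" %in% proto$stages) {
    out$matrix <- run_matrix(project, seed = proto$seed,
      params = proto$learner_params)
  }
  out
}

# Replay a stored prep_spec on a raw dataset (chemistry + response steps),
# reproducing the prepared dataset.
apply_prep_spec <- function(dataset, spec, positive_class = NULL) {
  meta <- dataset_meta(dataset)
  rec <- as_tibble(dataset)
  rp <- replay_prep(spec, rec$smiles_raw, rec$response_raw)
  keep <- !is.na(rp$smiles_std)
  meta$excluded <- dplyr::bind_rows(meta$excluded,
    tibble(record_id = rec$record_id[!keep], reason = rp$fail_reason[!keep]))
  rec <- rec[keep, ]
  rec$smiles_std <- rp$smiles_std[keep]
  if ("response" %in% names(rp)) rec$response <- rp$response[keep]
  if (any(vapply(spec, function(s) s$name == "categorize", logical(1)))) {
    meta$endpoint_type <- "categorical"
    meta$label_set <- sort(unique(rec$response))
  }
  meta$positive_class <- positive_class %||% meta$positive_class
  meta$prep_spec <- spec
  meta$prep_log <- vapply(spec, `[[`, character(1), "name")
  with_meta(rec, meta)
}

# ---- external validation -------------------------------------------------

#' Validate a model on an external dataset
#'
#' Applies the preparation spec of the training data to the external
#' records, computes descriptors with the same configuration and scores
#' the fitted model; the external set is never used to refit. Records
#' failing preparation are reported per record.
#'
#' @param result a built `qsar_model_result`.
#' @param project the project the model was built in.
#' @param external a raw `qsar_dataset` (same endpoint semantics).
#' @return list with `stats` (a ValidationStats list), `predictions`
#'   tibble and `failed` tibble of per-record preparation errors.
#' @export
external_validate <- function(result, project, external) {
  assert_that(result$status == "built", "model was not built")
  assert_that(nrow(external) > 0, "external dataset is empty")
  prepped <- apply_prep_spec(external, prep_spec(project$dataset),
    positive_class = attr(project$dataset, "positive_class"))
  failed <- attr(prepped, "excluded")
  ep <- endpoint_type(project$dataset)
  if (ep == "categorical") {
    labels <- attr(project$dataset, "label_set")
    bad <- !prepped$response %in% labels
    if (any(bad)) {
      failed <- dplyr::bind_rows(failed, tibble(
        record_id = prepped$record_id[bad],
        reason = paste("unmappable category:", prepped$response[bad])))
      prepped <- prepped[!bad, ]
    }
  }
  assert_that(nrow(prepped) > 0, "no external records survived preparation")
  desc <- compute_descriptors(prepped,
    blocks = project$descriptors$provenance$blocks,
    fold_width = project$descriptors$provenance$fold_width)
  blocks <- project$subsets$blocks[[
    match(result$subset_label, project$subsets$label)]]
  X <- subset_matrix(desc, blocks, prepped$record_id)
  pr <- predict_learner(result$fitted_model, X)
  y <- if (ep == "categorical") as.character(prepped$response)
    else as.numeric(prepped$response)
  stats <- validation_stats(y, pr$pred, pr$score, ep,
    result$fitted_model$positive_class)
  list(
    stats = stats,
    predictions = tibble(record_id = prepped$record_id, observed = y,
      predicted = pr$pred,
      score = if (is.null(pr$score)) NA_real_ else pr$score),
    failed = failed
  )
}
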