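# Model publication: freeze a built model into a self-contained bundle
# that replays data preparation at prediction time, generate its report,
# and serve predictions through a simple project registry.

#' Publish a built model
#'
#' Freezes a built model-matrix cell into a self-contained bundle:
#' preparation spec (with fitted constants), descriptor configuration,
#' fitted model, provenance triple, statistics snapshot, per-column
#' training descriptor ranges and an auto-generated report. The bundle is
#' persisted under the project registry and listed there.
#'
#' @param result a built `qsar_model_result`.
#' @param project the `qsar_project` the model was built in.
#' @param registry_dir registry directory (default
#'   `file.path(project$path, "published")`).
#' @return a `qsar_bundle`.
#' @export
publish <- function(result, project, registry_dir = file.path(project$path, "published")) {
  assert_that(inherits(result, "qsar_model_result"), "not a model result")
  assert_that(result$status == "built", "cannot publish a failed model")
  dir.create(registry_dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- project$subsets$blocks[[
    match(result$subset_label, project$subsets$label)]]
  X <- subset_matrix(project$descriptors, blocks,
    project$dataset$record_id)
  tr <- result$predictions$train$record_id
  Xtr <- X[tr, , drop = FALSE]
  ranges <- tibble(
    column = colnames(Xtr),
    min = apply(Xtr, 2, min), max = apply(Xtr, 2, max)
  )
  train_structures <- as_tibble(project$dataset)[
    match(tr, project$dataset$record_id),
    c("record_id", "smiles_raw", "smiles_std")]
  content <- list(
    prep_spec = prep_spec(project$dataset),
    descriptor_config = list(blocks = blocks,
      fold_width = project$descriptors$provenance$fold_width),
    provenance = list(split = result$split_label, subset = result$subset_label,
      learner = result$learner_name, model_id = result$model_id),
    endpoint_type = endpoint_type(project$dataset),
    positive_class = attr(project$dataset, "positive_class"),
    dataset_digest = dataset_digest(project$dataset),
    train_stats = result$train_stats, test_stats = result$test_stats,
    training_ranges = ranges,
    training_predictions = result$predictions$train,
    train_structures = train_structures
  )
  digest <- stable_id(content[c("prep_spec", "descriptor_config",
    "provenance", "dataset_digest")])
  existing <- list.dirs(registry_dir, recursive = FALSE, full.names = FALSE)
  k <- sum(grepl(paste0("^", digest), existing)) + 1L
  bundle_id <- sprintf("%s_%03d", digest, k)
  bundle <- structure(
    c(list(bundle_id = bundle_id, content_digest = digest,
      fitted_model = result$fitted_model), content),
    class = "qsar_bundle"
  )
  bundle$report <- generate_report(bundle)
  bdir <- file.path(registry_dir, bundle_id)
  dir.create(bdir, showWarnings = FALSE)
  saveRDS(bundle, file.path(bdir, "bundle.rds"))
  writeLines(bundle$report, file.path(bdir, "report.md"))
  yaml::write_yaml(list(
    bundle_id = bundle_id, content_digest = digest,
    endpoint_type = bundle$endpoint_type,
    provenance = bundle$provenance,
    published = TRUE
  ), file.path(bdir, "manifest.yaml"))
  bundle
}

#' @export
print.qsar_bundle <- function(x, ...) {
  cat(sprintf("<qsar_bundle> %s: %s / %s / %s (%s endpoint)\n",
    x$bundle_id, x$provenance$split, x$provenance$subset,
    x$provenance$learner, x$endpoint_type))
  invisible(x)
}

#' Load a published bundle
#'
#' @param registry_dir the registry directory.
#' @param bundle_id the bundle to load (or a bare name prefix).
#' @return a `qsar_bundle`.
#' @export
load_bundle <- function(registry_dir, bundle_id) {
  listing <- list_published(registry_dir)
  if (!bundle_id %in% listing$bundle_id) {
    abort(sprintf("unknown bundle '%s'; available: %s", bundle_id,
      if (nrow(listing)) paste(listing$bundle_id, collapse = ", ") else "(none)"))
  }
  readRDS(file.path(registry_dir, bundle_id, "bundle.rds"))
}

#' List published models
#'
#' @param registry_dir the registry directory.
#' @return tibble with `bundle_id`, `endpoint_type`, `split`, `subset`,
#'   `learner`.
#' @export
list_published <- function(registry_dir) {
  if (!dir.exists(registry_dir)) {
    return(tibble(bundle_id = character(), endpoint_type = character(),
      split = character(), subset = character(), learner = character()))
  }
  dirs <- list.dirs(registry_dir, recursive = FALSE)
  rows <- purrr::map(dirs, function(d) {
    mf <- file.path(d, "manifest.yaml")
    if (!file.exists(mf)) return(NULL)
    m <- yaml::read_yaml(mf)
    tibble(bundle_id = m$bundle_id, endpoint_type = m$endpoint_type,
      split = m$provenance$split, subset = m$provenance$subset,
      learner = m$provenance$learner)
  })
  dplyr::bind_rows(rows)
}

#' Predict activities with a published bundle
#'
#' Raw structures are standardised and descriptors computed exactly per
#' the bundle configuration before scoring, so salt forms and
#' non-canonical inputs give identical predictions to their standardised
#' forms. Each record gets an applicability warning count: the number of
#' descriptor columns falling outside the training range. Unparsable
#' structures yield per-record error entries; the batch continues.
#'
#' @param object a `qsar_bundle`.
#' @param structures character vector of SMILES (optionally named by
#'   record id).
#' @param ... unused.
#' @return tibble with `record_id`, `smiles`, `prediction`, `score`,
#'   `n_out_of_range`, `out_of_range` (list of column names), `error`.
#' @export
predict.qsar_bundle <- function(object, structures, ...) {
  ids <- names(structures) %||% sprintf("ext%04d", seq_along(structures))
  rp <- replay_prep(object$prep_spec, unname(structures))
  ok <- !is.na(rp$smiles_std)
  n <- length(structures)
  cat_ep <- object$endpoint_type == "categorical"
  out <- tibble(
    record_id = ids, smiles = unname(structures),
    prediction = if (cat_ep) rep(NA_character_, n) else rep(NA_real_, n),
    score = rep(NA_real_, n),
    n_out_of_range = rep(NA_integer_, n),
    out_of_range = vector("list", n),
    error = ifelse(ok, NA_character_,
      rp$fail_reason %||% "failed to standardise")
  )
  if (!any(ok)) return(out)
  std <- rp$smiles_std[ok]
  tmp <- new_qsar_dataset(
    tibble(record_id = ids[ok], smiles_raw = unname(structures)[ok],
      smiles_std = std, response_raw = NA, response = NA),
    endpoint_type = object$endpoint_type,
    positive_class = object$positive_class)
  desc <- compute_descriptors(tmp, blocks = object$descriptor_config$blocks,
    fold_width = object$descriptor_config$fold_width)
  computed <- desc$record_ids
  X <- subset_matrix(desc, object$descriptor_config$blocks, computed)
  pr <- predict_learner(object$fitted_model, X)
  rng <- object$training_ranges
  stopifnot(identical(rng$column, colnames(X)))
  below <- sweep(X, 2, rng$min, "<")
  above <- sweep(X, 2, rng$max, ">")
  oob <- below | above
  idx <- match(computed, out$record_id)
  out$prediction[idx] <- if (cat_ep) as.character(pr$pred) else as.numeric(pr$pred)
  if (!is.null(pr$score)) out$score[idx] <- pr$score
  out$n_out_of_range[idx] <- as.integer(rowSums(oob))
  out$out_of_range[idx] <- purrr::map(seq_along(computed), function(i)
    colnames(X)[oob[i, ]])
  lost <- setdiff(ids[ok], computed)
  out$error[match(lost, out$record_id)] <- "descriptor computation failed"
  out
}

#' Generate the model report
#'
#' A deterministic structured-text (markdown) report with the full model
#' building provenance: preparation steps, split definition, descriptor
#' configuration, learner and parameters, train/test statistics with the
#' confusion matrix (categorical) or regression summary (continuous),
#' and, for recursive-partitioning tree models, the descriptor-usage
#' frequency table ("Number of Questions" per descriptor).
#'
#' @param bundle a `qsar_bundle`.
#' @return character vector of report lines.
#' @export
generate_report <- function(bundle) {
  prov <- bundle$provenance
  fmt <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.4f", x)
  lines <- c(
    sprintf("# Model report: %s / %s / %s", prov$split, prov$subset, prov$learner),
    "",
    "## Data provenance and preparation",
    sprintf("- dataset digest: %s", bundle$dataset_digest),
    sprintf("- endpoint type: %s", bundle$endpoint_type),
    if (!is.null(bundle$positive_class))
      sprintf("- positive class: %s", bundle$positive_class),
    "- preparation steps:",
    vapply(bundle$prep_spec, function(s) paste0("    1. ", s$name), character(1)),
    "",
    "## Split definition",
    sprintf("- split label: %s", prov$split),
    sprintf("- training records: %d", nrow(bundle$training_predictions)),
    "",
    "## Descriptor configuration",
    sprintf("- blocks: %s", paste(bundle$descriptor_config$blocks, collapse = ", ")),
    sprintf("- fingerprint fold width: %d", bundle$descriptor_config$fold_width),
    "",
    "## Learner",
    sprintf("- learner: %s", prov$learner),
    sprintf("- parameters: %s", paste(names(bundle$fitted_model$params),
      unlist(lapply(bundle$fitted_model$params, paste, collapse = "/")),
      sep = "=", collapse = ", ") %||% "(defaults)")
  )
  if (bundle$endpoint_type == "categorical") {
    ts <- bundle$test_stats; tr <- bundle$train_stats
    lines <- c(lines, "",
      "## Statistics",
      "| set | TP | FP | TN | FN | sensitivity | specificity | ROC AUC |",
      "|---|---|---|---|---|---|---|---|",
      sprintf("| train | %d | %d | %d | %d | %s | %s | %s |",
        tr$tp, tr$fp, tr$tn, tr$fn, fmt(tr$sensitivity),
        fmt(tr$specificity), fmt(tr$roc_auc)),
      sprintf("| test | %d | %d | %d | %d | %s | %s | %s |",
        ts$tp, ts$fp, ts$tn, ts$fn, fmt(ts$sensitivity),
        fmt(ts$specificity), fmt(ts$roc_auc)))
  } else {
    ts <- bundle$test_stats; tr <- bundle$train_stats
    lines <- c(lines, "",
      "## Statistics",
      "| set | R2 | RMSE | REC area |",
      "|---|---|---|---|",
      sprintf("| train | %s | %s | %s |", fmt(tr$r_squared), fmt(tr$rmse),
        fmt(tr$rec_area)),
      sprintf("| test | %s | %s | %s |", fmt(ts$r_squared), fmt(ts$rmse),
        fmt(ts$rec_area)))
  }
  if (bundle$provenance$learner == "rp_tree") {
    usage <- tree_descriptor_usage(bundle$fitted_model)
    lines <- c(lines, "",
      "## Descriptor usage (Number of Questions)",
      "| descriptor | questions |",
      "|---|---|",
      sprintf("| %s | %d |", usage$descriptor, usage$questions))
  }
  lines
}

#' Descriptor-usage frequencies of a tree model
#'
#' Counts how many questions (internal tree splits) use each descriptor,
#' over all descriptors available to the model; unused descriptors are
#' reported with zero. Frequencies sum to the total number of questions.
#'
#' @param fit a `qsar_fit` with learner `rp_tree`.
#' @return tibble `descriptor`, `questions`, sorted by decreasing use.
#' @export
tree_descriptor_usage <- function(fit) {
  assert_that(fit$learner == "rp_tree", "descriptor usage requires an rp_tree fit")
  vars <- fit$fit$frame$var
  used <- table(as.character(vars[vars != "<leaf>"]))
  tibble(
    descriptor = fit$columns,
    questions = as.integer(ifelse(fit$columns %in% names(used),
      used[fit$columns], 0L))
  ) |>
    dplyr::arrange(dplyr::desc(.data$questions), .data$descriptor)
}
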