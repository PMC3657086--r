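# Model-matrix enumeration, failure isolation, resumability, protocols.

test_that("enumeration is the supported cartesian product in fixed order", {
  subsets <- default_subsets()
  splits <- c("Rand50", "Rand75", "IndOpt50", "IndOpt75", "RPC50", "RPC75",
    "FromFile")
  cat_specs <- enumerate_models(splits, subsets, learner_registry()$name,
    "categorical")
  expect_equal(nrow(cat_specs), 350)
  cont_specs <- enumerate_models(splits, subsets, learner_registry()$name,
    "continuous")
  expect_equal(nrow(cont_specs), 280)
  one <- enumerate_models("s", subsets[1, ], "svm", "categorical")
  expect_equal(nrow(one), 1)
  # deterministic ordering: split varies slowest, learner fastest
  expect_equal(cat_specs$split_label[1:50], rep("Rand50", 50))
  expect_error(enumerate_models(splits, subsets, "pls_nipals", "categorical"),
    "no learner supports")
  expect_equal(nrow(cat_specs),
    length(splits) * nrow(subsets) * 5)
})

small_project <- function() {
  ds <- cls_ds()
  splits <- list(
    Rand75 = random_split(ds, 0.75, seed = 21, label = "Rand75"),
    RPC75 = random_per_cluster_split(ds, cls_clusters(), 0.75, seed = 22,
      label = "RPC75")
  )
  subsets <- make_subsets(list(Molprops = "Molprops",
    ECFP6_Molprops = c("ECFP6", "Molprops")))
  project_set_stages(qsar_project(), ds, splits, cls_desc(), subsets)
}

test_that("a toy 2x2x2 matrix builds completely and is resumable", {
  proj <- small_project()
  specs <- enumerate_models(proj$splits, proj$subsets, c("rp_tree", "svm"),
    "categorical")
  expect_equal(nrow(specs), 8)
  mm <- run_matrix(proj, specs, seed = 31)
  expect_length(mm$results, 8)
  expect_true(all(vapply(mm$results, function(r) r$status, character(1)) == "built"))
  # rerun: cached results are reused identically (no retraining)
  files_before <- file.info(list.files(file.path(proj$path, "models"),
    full.names = TRUE))$mtime
  mm2 <- run_matrix(proj, specs, seed = 31)
  files_after <- file.info(list.files(file.path(proj$path, "models"),
    full.names = TRUE))$mtime
  expect_identical(files_before, files_after)
  expect_equal(triage(mm2), triage(mm))
})

test_that("a failing cell is captured as data and never disturbs other cells", {
  ds <- reg_ds()
  splits <- list(R = random_split(ds, 0.75, seed = 1, label = "R"))
  # a constant descriptor matrix makes PLS fail
  desc <- reg_desc()
  desc$blocks$Molprops_const <- desc$blocks$Molprops
  desc$blocks$Molprops_const[] <- 1
  # register the broken block under a subset by grafting the matrix in
  desc2 <- desc
  desc2$blocks$Chi <- desc$blocks$Molprops_const  # zero-variance "Chi"
  subsets <- make_subsets(list(Chi = "Chi", Molprops = "Molprops"))
  proj_ok <- project_set_stages(qsar_project(), ds, splits, desc, subsets)
  proj_bad <- project_set_stages(qsar_project(), ds, splits, desc2, subsets)
  specs <- enumerate_models(splits, subsets, c("pls_nipals", "svm"),
    "continuous")
  mm_ok <- run_matrix(proj_ok, specs, seed = 2)
  mm_bad <- run_matrix(proj_bad, specs, seed = 2)
  st_bad <- triage(mm_bad)
  expect_equal(st_bad$status[st_bad$subset_label == "Chi" &
    st_bad$learner_name == "pls_nipals"], "failed")
  expect_match(st_bad$failure_reason[st_bad$subset_label == "Chi" &
    st_bad$learner_name == "pls_nipals"], "variance|PLS")
  # the Molprops cells are bit-identical with and without the failing cell
  ok_tbl <- triage(mm_ok); bad_tbl <- triage(mm_bad)
  expect_equal(
    bad_tbl[bad_tbl$subset_label == "Molprops", c("learner_name", "test_r_squared", "test_rmse")],
    ok_tbl[ok_tbl$subset_label == "Molprops", c("learner_name", "test_r_squared", "test_rmse")])
})

test_that("matrix never ranks or drops models (no competitive selection)", {
  proj <- small_project()
  specs <- enumerate_models(proj$splits, proj$subsets,
    c("pp_bayes", "rp_tree"), "categorical")
  mm <- run_matrix(proj, specs, seed = 4)
  tbl <- triage(mm)
  # every attempted spec appears exactly once, in spec order
  expect_equal(nrow(tbl), nrow(specs))
  expect_equal(
    paste(tbl$split_label, tbl$subset_label, tbl$learner_name),
    paste(specs$split_label, specs$subset_label, specs$learner_name))
})

test_that("protocols capture the workflow and replay identically", {
  proj <- small_project()
  specs <- enumerate_models(proj$splits, proj$subsets, c("rp_tree", "pp_bayes"),
    "categorical")
  mm <- run_matrix(proj, specs, seed = 7)
  path <- tempfile(fileext = ".yaml")
  save_protocol(proj, c("prep", "split", "descriptors", "build"), path,
    seed = 7)
  raw <- generate_classification_set(120, seed = 7, noise = 0.1)
  out <- replay_protocol(path, raw)
  replay_tbl <- triage(out$matrix)
  orig_tbl <- triage(mm)
  shared <- intersect(names(replay_tbl), names(orig_tbl))
  key <- c("split_label", "subset_label", "learner_name")
  merged <- dplyr::inner_join(as_tibble(orig_tbl), as_tibble(replay_tbl),
    by = key, suffix = c("_a", "_b"))
  expect_equal(nrow(merged), nrow(orig_tbl))
  expect_equal(merged$test_roc_auc_a, merged$test_roc_auc_b)
  expect_equal(merged$train_roc_auc_a, merged$train_roc_auc_b)
})

test_that("prep-only protocols replay preparation alone", {
  proj <- small_project()
  path <- tempfile(fileext = ".yaml")
  save_protocol(proj, "prep", path)
  raw <- generate_classification_set(40, seed = 13)
  out <- replay_protocol(path, raw)
  expect_false(anyNA(out$project$dataset$smiles_std))
  expect_null(out$matrix)
})

test_that("protocol stage ranges must be contiguous and endpoints must match", {
  proj <- small_project()
  path <- tempfile(fileext = ".yaml")
  expect_error(save_protocol(proj, c("prep", "descriptors"), path),
    "contiguous")
  save_protocol(proj, c("prep", "split"), path)
  cont <- generate_regression_set(30, seed = 2)
  expect_error(replay_protocol(path, cont), "incompatible")
})

test_that("external validation on the test split reproduces the test stats", {
  proj <- small_project()
  specs <- enumerate_models(proj$splits, proj$subsets, "rp_tree", "categorical")
  mm <- run_matrix(proj, specs[1, ], seed = 3)
  res <- mm$results[[1]]
  ds <- proj$dataset
  ext_ids <- proj$splits[[res$split_label]]$test_ids
  idx <- match(ext_ids, ds$record_id)
  external <- new_test_dataset(ds$smiles_raw[idx],
    response = ds$response_raw[idx], endpoint_type = "categorical")
  ev <- external_validate(res, proj, external)
  expect_equal(ev$stats$roc_auc, res$test_stats$roc_auc)
  expect_equal(ev$stats$sensitivity, res$test_stats$sensitivity)
  # empty external set errors
  expect_error(external_validate(res, proj, external[0, ]), "empty")
})
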