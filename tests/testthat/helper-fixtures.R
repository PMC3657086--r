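# Shared fixtures, built once per test run and cached. The synthetic
# grammar's pairwise ECFP6 Tanimoto similarities are sparse compared with
# a lead-optimisation series, so the clustered fixtures use a 0.35
# similarity threshold (chosen from the grammar's similarity
# distribution) to obtain multi-member clusters.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cls_ds <- function() {
  cached("cls_ds", function() {
    standardize(generate_classification_set(120, seed = 7, noise = 0.1))
  })
}

cls_desc <- function() {
  cached("cls_desc", function() compute_descriptors(cls_ds(), fold_width = 256))
}

cls_clusters <- function() {
  cached("cls_clusters", function() {
    cluster_molecules(cls_ds(), similarity_threshold = 0.35,
      descriptors = cls_desc())
  })
}

reg_ds <- function() {
  cached("reg_ds", function() {
    standardize(generate_regression_set(100, seed = 11, noise_sd = 0.5))
  })
}

reg_desc <- function() {
  cached("reg_desc", function() compute_descriptors(reg_ds(), fold_width = 256))
}

# tiny deterministic classification matrix: separable on the first column
toy_class_data <- function(n = 40, seed = 5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 6), n, 6)
    colnames(X) <- paste0("d", 1:6)
    y <- ifelse(X[, 1] > 0, "pos", "neg")
    list(X = X, y = y)
  })
}

new_test_dataset <- function(smiles, response = seq_along(smiles),
                             endpoint_type = "continuous",
                             positive_class = NULL) {
  qsarmatrix:::new_qsar_dataset(
    tibble::tibble(
      record_id = paste0("m", seq_along(smiles)),
      smiles_raw = smiles, smiles_std = NA_character_,
      response_raw = response, response = response
    ),
    endpoint_type = endpoint_type, positive_class = positive_class,
    label_set = if (endpoint_type == "categorical") sort(unique(response))
  )
}

# rebuild a dataset with new raw structures (keeps responses)
with_raw <- function(ds, new_raw) {
  new_test_dataset(new_raw, response = ds$response,
    endpoint_type = endpoint_type(ds))
}

write_smiles_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
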