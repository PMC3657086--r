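# Dataset reading, chemistry standardisation and response preparation.

test_that("smiles_csv reading excludes bad records and reports them", {
  path <- write_smiles_csv(data.frame(
    id = c("a", "b", "c", "d"),
    smiles = c("CCO", "c1ccccc1", "CCN", "CCC"),
    BCF = c("1.2", "3.4", "", "5.6")
  ))
  ds <- read_dataset(path, "smiles_csv", response_field = "BCF",
    endpoint_type = "continuous")
  expect_s3_class(ds, "qsar_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(attr(ds, "load_report")$n_excluded, 1)
  expect_equal(attr(ds, "excluded")$reason, "missing response")
  expect_equal(ds$response_raw, c(1.2, 3.4, 5.6))
})

test_that("unparsable structures are excluded, zero records is an error", {
  path <- write_smiles_csv(data.frame(
    id = c("a", "b"), smiles = c("CCO", "not_a_structure"),
    response = c(1, 2)))
  ds <- read_dataset(path, "smiles_csv", endpoint_type = "continuous")
  expect_equal(nrow(ds), 1)
  expect_equal(attr(ds, "excluded")$reason, "unparsable structure")

  empty <- write_smiles_csv(data.frame(
    id = "a", smiles = "junk_smiles", response = 1))
  expect_error(
    read_dataset(empty, "smiles_csv", endpoint_type = "continuous"),
    "zero parsable records")
})

test_that("sdf reading pulls the response from a named tag", {
  sdf_lines <- c(
    "mol1",
    " synthetic fixture", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END",
    ">  <BCF>",
    "2.5", "",
    "$$$$"
  )
  path <- tempfile(fileext = ".sdf")
  writeLines(sdf_lines, path)
  ds <- read_dataset(path, "sdf", response_field = "BCF",
    endpoint_type = "continuous")
  expect_equal(nrow(ds), 1)
  expect_equal(ds$response_raw, 2.5)
})

test_that("desalting keeps the largest organic fragment", {
  ds <- new_test_dataset(c("CCO.Cl", "CCO", "CC(=O)[O-].[Na+]", "[Na+].[Cl-]"))
  std <- standardize(ds, c("desalt", "neutralize", "canonicalize"))
  expect_equal(nrow(std), 3)
  expect_equal(std$smiles_std[1], std$smiles_std[2])   # salt == clean form
  expect_equal(std$smiles_std[1], canonical_smiles("CCO"))
  # pure salt vanished with a logged reason
  expect_match(attr(std, "excluded")$reason, "desalting")
})

test_that("neutralisation gives the acid form the toolkit canonicalises to", {
  ds <- new_test_dataset("CC(=O)[O-].[Na+]")
  std <- standardize(ds)
  expect_equal(std$smiles_std, canonical_smiles("CC(=O)O"))
  # ammonium deprotonation, nitro untouched
  ds2 <- standardize(new_test_dataset(c("C[NH3+].[Cl-]", "c1ccc(cc1)[N+](=O)[O-]")))
  expect_equal(std2 <- ds2$smiles_std[1], canonical_smiles("CN"))
  expect_true(grepl("\\[N\\+\\]", ds2$smiles_std[2]))
})

test_that("standardisation is idempotent and logs every step in order", {
  ds <- standardize(new_test_dataset(c("CCO.Cl", "OCC", "c1ccccc1C(=O)[O-]")))
  again <- standardize(with_raw(ds, ds$smiles_std))
  expect_equal(again$smiles_std, ds$smiles_std)
  expect_equal(attr(ds, "prep_log"), c("desalt", "neutralize", "canonicalize"))
})

test_that("response transforms behave and store replay constants", {
  ds <- new_test_dataset(c("CCO", "CCC", "CCN"), response = c(100, 10, 1))
  lg <- transform_response(ds, "log10")
  expect_equal(lg$response, c(2, 1, 0))

  uv <- transform_response(ds, "unit_variance")
  expect_equal(sd(uv$response), 1)
  step <- prep_spec(uv)[[length(prep_spec(uv))]]
  expect_equal(step$params$center, mean(c(100, 10, 1)))

  bad <- new_test_dataset(c("CCO", "CCC"), response = c(1, 0))
  expect_error(transform_response(bad, "log10"), "m2")  # names the record
})

test_that("category mapping covers the five-class skin scheme and errors on gaps", {
  ds <- new_test_dataset(
    sprintf("C%sO", strrep("C", 1:5)),
    response = c("non", "weak", "moderate", "strong", "extreme"),
    endpoint_type = "categorical")
  map <- c(non = "non-sensitizer", weak = "non-sensitizer",
    moderate = "sensitizer", strong = "sensitizer", extreme = "sensitizer")
  out <- categorize_response(ds, mapping = map, positive_class = "sensitizer")
  expect_equal(endpoint_type(out), "categorical")
  expect_equal(sum(out$response == "non-sensitizer"), 2)
  expect_equal(sum(out$response == "sensitizer"), 3)
  expect_equal(nrow(out), nrow(ds))  # no silent drops
  expect_equal(attr(out, "positive_class"), "sensitizer")

  ds_bad <- new_test_dataset("CCO", response = "unknown",
    endpoint_type = "categorical")
  expect_error(categorize_response(ds_bad, mapping = map), "unknown")
})

test_that("threshold categorisation sends boundary values to the upper class", {
  ds <- new_test_dataset(c("CCO", "CCC", "CCN"), response = c(4.9, 5.0, 5.1))
  out <- categorize_response(ds, thresholds = 5.0,
    labels = c("low", "high"))
  expect_equal(out$response, c("low", "high", "high"))
  expect_error(
    categorize_response(ds, thresholds = c(5, 3), labels = c("a", "b", "c")),
    "strictly increasing")
})

test_that("replaying the prep spec reproduces the prepared dataset exactly", {
  ds <- generate_classification_set(30, seed = 3, salt_fraction = 0.3)
  prepped <- standardize(ds)
  replayed <- qsarmatrix:::apply_prep_spec(ds, prep_spec(prepped),
    positive_class = "active")
  expect_identical(replayed$smiles_std, prepped$smiles_std)
  expect_identical(replayed$response, prepped$response)

  # continuous pipeline with a response transform
  reg <- generate_regression_set(20, seed = 4)
  reg$response_raw <- abs(reg$response_raw) + 1
  reg$response <- reg$response_raw
  prepped2 <- transform_response(standardize(reg), "log10")
  replayed2 <- qsarmatrix:::apply_prep_spec(reg, prep_spec(prepped2))
  expect_identical(replayed2$response, prepped2$response)
})
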