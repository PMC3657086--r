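# Split construction, clustering and chemical-space diagnostics.

test_that("random split has exact counts and is seed-reproducible", {
  ds <- new_test_dataset(generate_molecules(8, seed = 1))
  sp <- random_split(ds, 0.75, seed = 42)
  expect_length(sp$train_ids, 6)
  expect_length(sp$test_ids, 2)
  sp2 <- random_split(ds, 0.75, seed = 42)
  expect_identical(sp$train_ids, sp2$train_ids)
  one <- new_test_dataset("CCO")
  expect_error(random_split(one, 0.5, seed = 1), "at least 2")
})

test_that("stratified split keeps per-class counts within one of target", {
  ds <- new_test_dataset(generate_molecules(20, seed = 2),
    response = rep(c("a", "b"), each = 10), endpoint_type = "categorical")
  sp <- stratified_split(ds, 0.5, seed = 9)
  tr <- as_tibble(sp)
  merged <- dplyr::inner_join(tr, tibble::as_tibble(ds)[, c("record_id", "response")],
    by = "record_id")
  counts <- table(merged$response, merged$set)
  expect_equal(unname(counts["a", "train"]), 5)
  expect_equal(unname(counts["b", "train"]), 5)

  # continuous: every quantile bin within one record of the target
  dsc <- new_test_dataset(generate_molecules(40, seed = 3), response = 1:40)
  spc <- stratified_split(dsc, 0.75, n_bins = 4, seed = 1)
  bins <- cut(1:40, breaks = quantile(1:40, seq(0, 1, 0.25)),
    include.lowest = TRUE)
  for (b in levels(bins)) {
    ids <- dsc$record_id[bins == b]
    n_tr <- sum(ids %in% spc$train_ids)
    expect_lte(abs(n_tr - 0.75 * length(ids)), 1)
  }
})

test_that("stratified assignments stay within the enumerated valid set (n=6, 2 bins)", {
  ds <- new_test_dataset(generate_molecules(6, seed = 4),
    response = rep(c("x", "y"), each = 3), endpoint_type = "categorical")
  # valid: within each class of 3, round(3 * 0.5) = 2 go to train
  valid <- list()
  cmb <- utils::combn(1:3, 2)
  for (i in seq_len(ncol(cmb))) for (j in seq_len(ncol(cmb))) {
    valid[[length(valid) + 1]] <- sort(ds$record_id[c(cmb[, i], 3 + cmb[, j])])
  }
  valid_keys <- vapply(valid, paste, character(1), collapse = ",")
  for (seed in 1:25) {
    sp <- stratified_split(ds, 0.5, seed = seed)
    expect_true(paste(sort(sp$train_ids), collapse = ",") %in% valid_keys)
  }
})

# independent re-implementation: sphere exclusion recomputing neighbour
# lists from scratch at every step
butina_oracle <- function(sim, threshold) {
  n <- nrow(sim)
  assigned <- rep(NA_integer_, n)
  k <- 0
  while (anyNA(assigned)) {
    open <- which(is.na(assigned))
    best <- open[1]; best_n <- -1
    for (i in open) {
      cnt <- sum(sim[i, open] >= threshold) - 1
      if (cnt > best_n) { best <- i; best_n <- cnt }
    }
    k <- k + 1
    members <- open[sim[best, open] >= threshold]
    assigned[unique(c(best, members))] <- k
  }
  assigned
}

test_that("butina clustering equals the brute-force sphere-exclusion oracle", {
  sub <- standardize(new_test_dataset(cls_ds()$smiles_std[1:10]))
  sim <- qsarmatrix:::similarity_for(sub, "ECFP6")
  got <- qsarmatrix:::butina_cluster(sim, 0.35, sub$record_id)
  want <- butina_oracle(sim, 0.35)
  # same partition (cluster indexing may differ)
  expect_equal(
    split(seq_along(got), got)[order(sapply(split(seq_along(got), got), min))],
    unname(split(seq_along(want), want)[order(sapply(split(seq_along(want), want), min))]),
    ignore_attr = TRUE)
})

test_that("duplicate structures share a cluster; dissimilar ones are singletons", {
  ds <- standardize(new_test_dataset(c("CCO", "CCO", "c1ccc2ccccc2c1")))
  cl <- cluster_molecules(ds, similarity_threshold = 0.7)
  expect_equal(cl[["m1"]], cl[["m2"]])
  expect_false(cl[["m3"]] == cl[["m1"]])
})

test_that("independent cluster split is exhaustive-optimal and never splits a cluster", {
  ds <- new_test_dataset(generate_molecules(10, seed = 5))
  cl <- setNames(rep(1:3, c(5, 3, 2)), ds$record_id)
  sp <- independent_cluster_split(ds, cl, train_fraction = 0.8, seed = 1)
  expect_setequal(sp$test_ids, ds$record_id[9:10])  # the size-2 cluster
  # invariant: no cluster on both sides
  expect_length(intersect(unique(cl[sp$train_ids]), unique(cl[sp$test_ids])), 0)
  expect_error(
    independent_cluster_split(ds, setNames(rep(1, 10), ds$record_id), 0.8, 1),
    "single cluster")
})

test_that("independent cluster split matches exhaustive search for <= 12 clusters", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      k <- sample(3:12, 1)
      sizes <- sample(1:8, k, replace = TRUE)
    })
    n <- sum(sizes)
    ds <- new_test_dataset(generate_molecules(n, seed = seed + 100))
    cl <- setNames(rep(seq_len(k), sizes), ds$record_id)
    frac <- sample(c(0.5, 0.75), 1)
    sp <- independent_cluster_split(ds, cl, frac, seed = seed)
    achieved <- abs(length(sp$test_ids) / n - (1 - frac))
    # exhaustive optimum over all whole-cluster test subsets
    best <- Inf
    for (m in 1:(2^k - 2)) {
      b <- as.logical(bitwAnd(m, 2^(0:(k - 1))))
      best <- min(best, abs(sum(sizes[b]) / n - (1 - frac)))
    }
    expect_equal(achieved, best, tolerance = 1e-12)
  }
})

test_that("random per cluster splits within clusters and handles singletons", {
  ds <- new_test_dataset(generate_molecules(4, seed = 6))
  cl <- setNames(rep(1, 4), ds$record_id)
  sp <- random_per_cluster_split(ds, cl, 0.75, seed = 2)
  expect_length(sp$train_ids, 3)
  sp2 <- random_per_cluster_split(ds, cl, 0.75, seed = 2)
  expect_identical(sp2$train_ids, sp$train_ids)

  # all singletons: Bernoulli assignment converges to the target
  n <- 1000
  dsb <- new_test_dataset(paste0("C", strrep("C", (0:(n - 1)) %% 7 + 1)))
  dsb$record_id <- paste0("r", 1:n)
  clb <- setNames(seq_len(n), dsb$record_id)
  fracs <- vapply(1:5, function(s) {
    spb <- random_per_cluster_split(dsb, clb, 0.75, seed = s)
    length(spb$train_ids) / n
  }, numeric(1))
  expect_true(all(fracs >= 0.70 & fracs <= 0.80))
})

test_that("predefined splits must cover the dataset exactly", {
  ds <- new_test_dataset(generate_molecules(6, seed = 7))
  path <- tempfile()
  writeLines(sprintf("%s %s", ds$record_id,
    rep(c("train", "test"), c(4, 2))), path)
  sp <- load_predefined_split(ds, path)
  expect_setequal(sp$train_ids, ds$record_id[1:4])
  expect_equal(sp$algorithm, "predefined")
  expect_equal(sp$train_fraction, 4 / 6)

  writeLines(sprintf("%s %s", ds$record_id[-1],
    rep(c("train", "test"), c(3, 2))), path)
  expect_error(load_predefined_split(ds, path), "missing")
  writeLines(c(sprintf("%s train", ds$record_id), "ghost test"), path)
  expect_error(load_predefined_split(ds, path), "unknown")
})

test_that("every split algorithm yields an exact partition (fuzzed seeds)", {
  ds <- standardize(new_test_dataset(cls_ds()$smiles_std[1:40],
    response = cls_ds()$response[1:40], endpoint_type = "categorical"))
  cl <- cluster_molecules(ds, similarity_threshold = 0.35)
  ids <- ds$record_id
  for (seed in 1:25) {
    sps <- list(
      random_split(ds, 0.7, seed),
      stratified_split(ds, 0.7, seed = seed),
      independent_cluster_split(ds, cl, 0.7, seed),
      random_per_cluster_split(ds, cl, 0.7, seed)
    )
    for (sp in sps) {
      expect_length(intersect(sp$train_ids, sp$test_ids), 0)
      expect_setequal(c(sp$train_ids, sp$test_ids), ids)
    }
  }
})

test_that("MDS embedding matches the double-centering eigendecomposition oracle", {
  ds <- standardize(new_test_dataset(generate_molecules(8, seed = 8)))
  sp <- random_split(ds, 0.75, seed = 1)
  an <- analyze_split(ds, sp)
  d <- 1 - qsarmatrix:::similarity_for(ds, "ECFP6")
  # classical MDS by hand: B = -1/2 J D^2 J, top-2 eigenpairs
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2)
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 0)))
  X <- as.matrix(an$coords[, c("x", "y")])
  # compare up to orthogonal transformation (Procrustes residual)
  sv <- svd(crossprod(oracle, X))
  R <- sv$u %*% t(sv$v)
  expect_lt(max(abs(oracle %*% R - X)), 1e-8)
})

test_that("duplicate structures embed at identical coordinates", {
  ds <- standardize(new_test_dataset(c("CCO", "CCO", "c1ccccc1", "CCCCN")))
  sp <- random_split(ds, 0.5, seed = 3)
  an <- analyze_split(ds, sp)
  expect_equal(unname(unlist(an$coords[1, c("x", "y")])),
    unname(unlist(an$coords[2, c("x", "y")])), tolerance = 1e-8)
  # degenerate all-identical case: zero coordinates with a warning
  dsd <- standardize(new_test_dataset(c("CCO", "CCO", "CCO")))
  spd <- random_split(dsd, 0.67, seed = 1)
  expect_warning(and <- analyze_split(dsd, spd), "identical")
  expect_true(all(and$coords$x == 0 & and$coords$y == 0))
})

test_that("three equidistant points embed as an equilateral triangle", {
  sim <- matrix(0.2, 3, 3); diag(sim) <- 1
  d <- 1 - sim
  mds <- stats::cmdscale(stats::as.dist(d), k = 2)
  emb <- as.matrix(stats::dist(mds))
  off <- emb[upper.tri(emb)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-8)
})

test_that("standard split set yields six generated splits plus one predefined", {
  ds <- cls_ds()
  splits <- standard_splits(ds, seed = 5, cluster_of = cls_clusters(),
    descriptors = cls_desc())
  expect_length(splits, 6)
  path <- tempfile()
  write_split(splits$Rand75, path)
  splits7 <- standard_splits(ds, seed = 5, cluster_of = cls_clusters(),
    descriptors = cls_desc(), predefined_path = path)
  expect_length(splits7, 7)
  expect_equal(sort(names(splits7)), sort(c("Rand50", "Rand75", "IndOpt50",
    "IndOpt75", "RPC50", "RPC75", "FromFile")))
})
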