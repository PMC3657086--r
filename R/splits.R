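# Train/test split construction and chemical-space split diagnostics.

new_split_assignment <- function(label, algorithm, train_ids, test_ids,
                                 all_ids, train_fraction = NA_real_,
                                 seed = NA_integer_, cluster_of = NULL,
                                 params = list()) {
  assert_that(length(intersect(train_ids, test_ids)) == 0,
    "train and test ids overlap")
  assert_that(setequal(c(train_ids, test_ids), all_ids),
    "split does not partition the record ids")
  assert_that(length(train_ids) > 0 && length(test_ids) > 0,
    "split leaves one side empty")
  structure(
    list(
      label = label, algorithm = algorithm,
      train_ids = train_ids, test_ids = test_ids,
      train_fraction = train_fraction, seed = seed,
      cluster_of = cluster_of, params = params
    ),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf(
    "<split_assignment> %s (%s): %d train / %d test (train fraction %.3f)\n",
    x$label, x$algorithm, length(x$train_ids), length(x$test_ids),
    length(x$train_ids) / (length(x$train_ids) + length(x$test_ids))
  ))
  invisible(x)
}

#' @export
as_tibble.split_assignment <- function(x, ...) {
  tibble(
    record_id = c(x$train_ids, x$test_ids),
    set = rep(c("train", "test"), c(length(x$train_ids), length(x$test_ids)))
  )
}

#' Random train/test split
#'
#' Samples `round(n * train_fraction)` records uniformly without
#' replacement into the training set; reproducible for a fixed seed.
#'
#' @param dataset a `qsar_dataset`.
#' @param train_fraction proportion in (0, 1).
#' @param seed integer seed.
#' @param label split label.
#' @return a `split_assignment`.
#' @export
random_split <- function(dataset, train_fraction, seed, label = "random") {
  ids <- dataset$record_id
  n <- length(ids)
  assert_that(n >= 2, "need at least 2 records to split")
  assert_that(train_fraction > 0 && train_fraction < 1,
    "train_fraction must be in (0, 1)")
  n_train <- round(n * train_fraction)
  assert_that(n_train >= 1 && n_train <= n - 1,
    "train_fraction leaves one side empty")
  withr::with_seed(seed, {
    train <- sample(ids, n_train)
  })
  new_split_assignment(label, "random", sort(train), sort(setdiff(ids, train)),
    ids, train_fraction, seed)
}

#' Stratified train/test split
#'
#' Bins the response (quantile bins for continuous endpoints, classes for
#' categorical) and applies a random split within each bin, keeping the
#' per-bin train fraction within one record of the target. Bins with
#' fewer than 2 records are merged with their neighbour with a warning.
#'
#' @inheritParams random_split
#' @param n_bins number of quantile bins for continuous endpoints.
#' @return a `split_assignment`.
#' @export
stratified_split <- function(dataset, train_fraction, n_bins = 5, seed,
                             label = "stratified") {
  ids <- dataset$record_id
  n <- length(ids)
  assert_that(n >= 2, "need at least 2 records to split")
  if (endpoint_type(dataset) == "categorical") {
    bin <- as.integer(factor(dataset$response))
  } else {
    y <- as.numeric(dataset$response)
    qs <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- findInterval(y, qs[-c(1, length(qs))]) + 1L
  }
  # merge undersized bins with the nearest lower bin
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < 2]
    if (!length(small) || length(tab) == 1) break
    b <- as.integer(small[1])
    others <- setdiff(as.integer(names(tab)), b)
    target <- others[which.min(abs(others - b))]
    warn(sprintf("stratified_split: merging undersized bin %d into %d", b, target))
    bin[bin == b] <- target
  }
  train <- character()
  withr::with_seed(seed, {
    for (b in sort(unique(bin))) {
      in_bin <- ids[bin == b]
      k <- round(length(in_bin) * train_fraction)
      k <- max(1L, min(length(in_bin) - 1L, k))
      train <- c(train, sample(in_bin, k))
    }
  })
  new_split_assignment(label, "stratified", sort(train),
    sort(setdiff(ids, train)), ids, train_fraction, seed,
    params = list(n_bins = n_bins))
}

#' Sphere-exclusion (Butina-style) clustering
#'
#' Clusters records on fingerprint Tanimoto similarity (or unit-scaled
#' property-space distance). At each step the unassigned record with the
#' most unassigned neighbours within the similarity threshold becomes a
#' cluster centroid and claims those neighbours; ties break to the
#' earliest record in input order. Singleton clusters are allowed.
#'
#' @param dataset a standardised `qsar_dataset`.
#' @param fingerprint_kind `"ECFP6"`, `"FCFP4"` (Tanimoto on raw
#'   identifier sets) or `"Molprops"` (similarity `1/(1 + d)` with `d` the
#'   Euclidean distance over unit-scaled property columns).
#' @param similarity_threshold neighbours are records with similarity at
#'   or above this value (default 0.7).
#' @param descriptors optional precomputed `descriptor_set` covering the
#'   needed block.
#' @return named integer vector: record_id -> cluster index (1-based,
#'   in order of cluster creation).
#' @export
cluster_molecules <- function(dataset, fingerprint_kind = "ECFP6",
                              similarity_threshold = 0.7,
                              descriptors = NULL) {
  sim <- similarity_for(dataset, fingerprint_kind, descriptors)
  out <- butina_cluster(sim, similarity_threshold, dataset$record_id)
  attr(out, "fingerprint_kind") <- fingerprint_kind
  attr(out, "similarity_threshold") <- similarity_threshold
  out
}

similarity_for <- function(dataset, fingerprint_kind, descriptors = NULL) {
  ids <- dataset$record_id
  if (fingerprint_kind %in% c("ECFP6", "FCFP4")) {
    if (is.null(descriptors) ||
        is.null(descriptors$fp_ids[[fingerprint_kind]])) {
      descriptors <- compute_descriptors(dataset, blocks = fingerprint_kind,
        fold_width = 64)
    }
    sets <- descriptors$fp_ids[[fingerprint_kind]][ids]
    assert_that(!any(vapply(sets, is.null, logical(1))),
      "fingerprints not computable for all records")
    sim <- tanimoto_matrix(sets)
  } else if (fingerprint_kind == "Molprops") {
    if (is.null(descriptors) || is.null(descriptors$blocks$Molprops)) {
      descriptors <- compute_descriptors(dataset, blocks = "Molprops")
    }
    m <- descriptors$blocks$Molprops[ids, , drop = FALSE]
    m <- scale(m)
    m[, apply(is.na(m), 2, any)] <- 0
    sim <- 1 / (1 + as.matrix(stats::dist(m)))
  } else {
    abort(sprintf("unknown fingerprint kind: %s", fingerprint_kind))
  }
  dimnames(sim) <- list(ids, ids)
  sim
}

cluster_params_of <- function(cluster_of) {
  list(
    fingerprint_kind = attr(cluster_of, "fingerprint_kind") %||% "ECFP6",
    similarity_threshold = attr(cluster_of, "similarity_threshold") %||% 0.7
  )
}

# sphere exclusion with neighbour lists recomputed among unassigned
# records at every step
butina_cluster <- function(sim, threshold, ids) {
  n <- nrow(sim)
  neighbour <- sim >= threshold
  diag(neighbour) <- FALSE
  cluster <- rep(NA_integer_, n)
  next_cl <- 1L
  while (anyNA(cluster)) {
    open <- which(is.na(cluster))
    counts <- rowSums(neighbour[open, open, drop = FALSE])
    centroid <- open[which.max(counts)]  # which.max -> earliest on ties
    members <- open[neighbour[centroid, open]]
    cluster[c(centroid, members)] <- next_cl
    next_cl <- next_cl + 1L
  }
  stats::setNames(cluster, ids)
}

#' Independent-clusters (optimized) split
#'
#' Assigns whole clusters to the test set so that the achieved test
#' fraction is as close as possible to `1 - train_fraction`; no cluster
#' ever spans both sides, so test chemistry is deliberately dissimilar to
#' training chemistry. For up to 16 clusters the optimal whole-cluster
#' subset is found by exhaustive enumeration; beyond that a greedy
#' descending-size assignment with single-cluster swap improvement is
#' used. Ties between equally good subsets break by seed-determined
#' order.
#'
#' @inheritParams random_split
#' @param cluster_of named integer vector from [cluster_molecules()].
#' @return a `split_assignment` (carries `cluster_of`).
#' @export
independent_cluster_split <- function(dataset, cluster_of, train_fraction,
                                      seed, label = "indopt") {
  ids <- dataset$record_id
  assert_that(all(ids %in% names(cluster_of)), "cluster_of must cover all records")
  cl <- cluster_of[ids]
  sizes <- table(cl)
  k <- length(sizes)
  assert_that(k >= 2, "cannot form independent split: single cluster")
  n <- length(ids)
  target <- 1 - train_fraction
  cl_names <- names(sizes)
  sz <- as.numeric(sizes)

  if (k <= 16) {
    masks <- seq_len(2^k - 2)  # exclude empty and full test sets
    withr::with_seed(seed, masks <- sample(masks))
    bits <- function(m) as.logical(bitwAnd(m, 2^(0:(k - 1))))
    best <- NULL; best_err <- Inf
    for (m in masks) {
      b <- bits(m)
      err <- abs(sum(sz[b]) / n - target)
      if (err < best_err - 1e-12) {
        best_err <- err; best <- b
      }
    }
    test_cl <- cl_names[best]
  } else {
    ord <- withr::with_seed(seed, sample(k))
    ord <- ord[order(-sz[ord])]  # descending size, seed-broken ties
    test_cl <- character(); test_n <- 0
    for (i in ord) {
      if (abs((test_n + sz[i]) / n - target) < abs(test_n / n - target)) {
        test_cl <- c(test_cl, cl_names[i]); test_n <- test_n + sz[i]
      }
    }
    if (!length(test_cl)) {
      i <- ord[which.min(abs(sz[ord] / n - target))]
      test_cl <- cl_names[i]; test_n <- sz[i]
    }
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(k)) {
        nm <- cl_names[i]
        in_test <- nm %in% test_cl
        cand_n <- test_n + if (in_test) -sz[i] else sz[i]
        if (cand_n <= 0 || cand_n >= n) next
        if (abs(cand_n / n - target) < abs(test_n / n - target) - 1e-12) {
          test_cl <- if (in_test) setdiff(test_cl, nm) else c(test_cl, nm)
          test_n <- cand_n; improved <- TRUE
        }
      }
    }
  }
  test <- ids[cl %in% test_cl]
  new_split_assignment(label, "independent_clusters_optimized",
    sort(setdiff(ids, test)), sort(test), ids, train_fraction, seed,
    cluster_of = cl, params = cluster_params_of(cluster_of))
}

#' Random-per-cluster split
#'
#' Within each cluster of size >= 2, samples `round(size *
#' train_fraction)` members into the training set; singleton clusters are
#' assigned by a seed-determined Bernoulli(`train_fraction`) draw. Test
#' chemistry stays similar to training chemistry because every cluster
#' contributes to both sides where it can.
#'
#' @inheritParams independent_cluster_split
#' @return a `split_assignment` (carries `cluster_of`).
#' @export
random_per_cluster_split <- function(dataset, cluster_of, train_fraction,
                                     seed, label = "rpc") {
  ids <- dataset$record_id
  assert_that(all(ids %in% names(cluster_of)), "cluster_of must cover all records")
  cl <- cluster_of[ids]
  train <- character()
  withr::with_seed(seed, {
    for (c_i in sort(unique(cl))) {
      members <- ids[cl == c_i]
      if (length(members) == 1) {
        if (stats::runif(1) < train_fraction) train <- c(train, members)
      } else {
        n_tr <- round(length(members) * train_fraction)
        n_tr <- max(1L, min(length(members) - 1L, n_tr))
        train <- c(train, sample(members, n_tr))
      }
    }
  })
  # guard: Bernoulli draws can empty one side in tiny all-singleton data
  if (length(train) == 0) train <- ids[1]
  if (length(train) == length(ids)) train <- train[-length(train)]
  new_split_assignment(label, "random_per_cluster", sort(train),
    sort(setdiff(ids, train)), ids, train_fraction, seed, cluster_of = cl,
    params = cluster_params_of(cluster_of))
}

#' Load a predefined split from a file
#'
#' Reads a two-column delimited table (`record_id`, `train`/`test`) that
#' must cover every record of the dataset exactly; any missing or unknown
#' ids are reported as an error.
#'
#' @param dataset a `qsar_dataset`.
#' @param path file with columns `record_id` and `set` (header optional;
#'   whitespace-, comma- or tab-delimited).
#' @param label split label (default `"from_file"`).
#' @return a `split_assignment` with the fraction derived from the file.
#' @export
load_predefined_split <- function(dataset, path, label = "from_file") {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = FALSE, sep = "",
    stringsAsFactors = FALSE, col.names = c("record_id", "set"),
    colClasses = "character")
  if (tolower(raw$record_id[1]) %in% c("record_id", "id")) raw <- raw[-1, ]
  raw$set <- tolower(raw$set)
  assert_that(all(raw$set %in% c("train", "test")),
    "split file values must be 'train' or 'test'")
  ids <- dataset$record_id
  missing_ids <- setdiff(ids, raw$record_id)
  extra_ids <- setdiff(raw$record_id, ids)
  assert_that(length(missing_ids) == 0 && length(extra_ids) == 0, sprintf(
    "split file does not match dataset%s%s",
    if (length(missing_ids)) paste0("; missing: ",
      paste(utils::head(missing_ids, 5), collapse = ", ")) else "",
    if (length(extra_ids)) paste0("; unknown: ",
      paste(utils::head(extra_ids, 5), collapse = ", ")) else ""))
  train <- raw$record_id[raw$set == "train"]
  test <- raw$record_id[raw$set == "test"]
  new_split_assignment(label, "predefined", sort(train), sort(test), ids,
    train_fraction = length(train) / length(ids))
}

#' Write a split assignment to a file
#'
#' @param assignment a `split_assignment`.
#' @param path output path (two-column whitespace-delimited text).
#' @return `path`, invisibly.
#' @export
write_split <- function(assignment, path) {
  utils::write.table(as_tibble(assignment), path, row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chemical-space analysis of a split
#'
#' Embeds the records in two dimensions by classical (metric)
#' multidimensional scaling of the Tanimoto distance matrix (`1 -
#' similarity`) and summarises train/test overlap as each test record's
#' nearest-training-neighbour similarity. Whole-cluster splits show up as
#' test "islands"; within-cluster splits as interspersed test points.
#'
#' @param dataset a standardised `qsar_dataset` (>= 3 records).
#' @param assignment a `split_assignment` for this dataset.
#' @param fingerprint_kind similarity space, as in [cluster_molecules()].
#' @param descriptors optional precomputed `descriptor_set`.
#' @return a `split_analysis`: list with `coords` (tibble: record_id,
#'   set, x, y), `stress`, `overlap` (per-test-record tibble) and
#'   `mean_nn_similarity`.
#' @export
analyze_split <- function(dataset, assignment, fingerprint_kind = "ECFP6",
                          descriptors = NULL) {
  ids <- dataset$record_id
  assert_that(length(ids) >= 3, "need at least 3 records")
  sim <- similarity_for(dataset, fingerprint_kind, descriptors)
  d <- 1 - sim
  if (all(d < 1e-12)) {
    warn("all records identical in this similarity space; coordinates set to 0")
    coords <- matrix(0, length(ids), 2)
    stress <- 0
  } else {
    mds <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
    coords <- mds$points
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
    emb <- as.matrix(stats::dist(coords))
    stress <- sqrt(sum((emb - d)^2) / sum(d^2))
  }
  set <- ifelse(ids %in% assignment$train_ids, "train", "test")
  test_idx <- which(set == "test")
  train_idx <- which(set == "train")
  nn_sim <- vapply(test_idx, function(i) max(sim[i, train_idx]), numeric(1))
  structure(
    list(
      coords = tibble(record_id = ids, set = set,
        x = coords[, 1], y = coords[, 2]),
      stress = stress,
      overlap = tibble(record_id = ids[test_idx], nn_similarity = nn_sim),
      mean_nn_similarity = mean(nn_sim),
      label = assignment$label
    ),
    class = "split_analysis"
  )
}

#' @export
print.split_analysis <- function(x, ...) {
  cat(sprintf(
    "<split_analysis> %s: MDS stress %.3f, mean nearest-train similarity of test records %.3f\n",
    x$label, x$stress, x$mean_nn_similarity
  ))
  invisible(x)
}

#' Build the standard split set
#'
#' Three algorithms (random, independent clusters optimized, random per
#' cluster) at two training percentages (50 and 75) gives six splits;
#' an optional predefined split file adds a seventh.
#'
#' @param dataset a standardised `qsar_dataset`.
#' @param seed integer seed (per-split seeds are derived from it).
#' @param fractions training fractions (default `c(0.5, 0.75)`).
#' @param predefined_path optional predefined split file.
#' @param cluster_of optional precomputed clustering; computed at the
#'   default ECFP6/0.7 settings when absent.
#' @param descriptors optional precomputed `descriptor_set`.
#' @return named list of `split_assignment`s.
#' @export
standard_splits <- function(dataset, seed, fractions = c(0.5, 0.75),
                            predefined_path = NULL, cluster_of = NULL,
                            descriptors = NULL) {
  if (is.null(cluster_of)) {
    cluster_of <- cluster_molecules(dataset, descriptors = descriptors)
  }
  splits <- list()
  for (f in fractions) {
    pct <- round(100 * f)
    splits[[paste0("Rand", pct)]] <- random_split(
      dataset, f, derive_seed(seed, paste0("rand", pct)), paste0("Rand", pct))
    splits[[paste0("IndOpt", pct)]] <- independent_cluster_split(
      dataset, cluster_of, f, derive_seed(seed, paste0("indopt", pct)),
      paste0("IndOpt", pct))
    splits[[paste0("RPC", pct)]] <- random_per_cluster_split(
      dataset, cluster_of, f, derive_seed(seed, paste0("rpc", pct)),
      paste0("RPC", pct))
  }
  if (!is.null(predefined_path)) {
    splits[["FromFile"]] <- load_predefined_split(dataset, predefined_path,
      label = "FromFile")
  }
  splits
}
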