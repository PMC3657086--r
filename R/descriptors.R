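# Descriptor blocks: molecular properties, Kier-Hall chi connectivity
# indices, electrotopological state (E-state) values/counts, and
# ECFP6/FCFP4 circular fingerprints. All engines operate on the heavy-atom
# molecular graph (mol-graph.R); ALogP, molecular weight and H-bond counts
# are taken from OpenBabel's atomic-contribution models via ChemmineOB.

.molprops_names <- c(
  "ALogP", "Molecular_Weight", "Num_RotatableBonds", "Num_Bonds",
  "Num_Atoms", "Num_H_Acceptors", "Num_H_Acceptors_Lipinski", "HBA_Count",
  "Num_H_Donors_Lipinski", "HBD_Count", "Num_H_Donors", "Num_Rings",
  "Num_StereoBonds", "Num_AromaticBonds", "Num_AromaticRings",
  "Num_StereoAtoms", "Num_BridgeBonds", "Num_BridgeHeadAtoms",
  "Num_SpiroAtoms"
)

# ---- ring topology counts ------------------------------------------------

ring_topology_counts <- function(g) {
  rings <- g$rings
  n_spiro <- 0L
  bridgeheads <- integer()
  bridge_bonds <- character()
  if (length(rings) >= 2) {
    spiro_atoms <- integer()
    for (i in seq_len(length(rings) - 1)) {
      for (j in seq(i + 1, length(rings))) {
        shared <- intersect(rings[[i]], rings[[j]])
        if (length(shared) == 1) {
          spiro_atoms <- c(spiro_atoms, shared)
        } else if (length(shared) >= 3) {
          # rings sharing a path of >= 2 bonds: a bridged system
          sb <- g$bonds[g$bonds$a1 %in% shared & g$bonds$a2 %in% shared, ]
          nb_in_shared <- vapply(shared, function(a)
            sum(sb$a1 == a | sb$a2 == a), integer(1))
          bridgeheads <- c(bridgeheads, shared[nb_in_shared == 1])
          bridge_bonds <- c(bridge_bonds, paste(sb$a1, sb$a2))
        }
      }
    }
    n_spiro <- length(unique(spiro_atoms))
  }
  list(
    n_spiro = n_spiro,
    n_bridgehead = length(unique(bridgeheads)),
    n_bridge_bonds = length(unique(bridge_bonds))
  )
}

count_stereo_atoms <- function(smiles) {
  m <- gregexpr("@+", smiles)[[1]]
  if (m[1] == -1) 0L else length(m)
}

count_stereo_bonds <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  eq <- which(chars == "=")
  if (!length(eq)) return(0L)
  sum(vapply(eq, function(i) {
    win <- chars[max(1, i - 3):min(length(chars), i + 3)]
    any(win %in% c("/", "\\"))
  }, logical(1)))
}

# ---- Molprops ------------------------------------------------------------

molprops_from_graph <- function(g, ob) {
  bonds <- g$bonds
  rot <- if (nrow(bonds)) sum(
    bonds$order == 1 & !bonds$in_ring &
      g$degree[bonds$a1] >= 2 & g$degree[bonds$a2] >= 2
  ) else 0L
  n_comp <- igraph::components(g$graph)$no
  topo <- ring_topology_counts(g)
  c(
    ALogP = as.numeric(ob[["logP"]]),
    Molecular_Weight = as.numeric(ob[["MW"]]),
    Num_RotatableBonds = rot,
    Num_Bonds = nrow(bonds),
    Num_Atoms = g$n,
    Num_H_Acceptors = as.numeric(ob[["HBA2"]]),
    Num_H_Acceptors_Lipinski = sum(g$symbol %in% c("N", "O")),
    HBA_Count = as.numeric(ob[["HBA1"]]),
    Num_H_Donors_Lipinski = sum(g$nH[g$symbol %in% c("N", "O")]),
    HBD_Count = sum(g$symbol %in% c("N", "O", "S") & g$nH > 0),
    Num_H_Donors = as.numeric(ob[["HBD"]]),
    Num_Rings = nrow(bonds) - g$n + n_comp,
    Num_StereoBonds = count_stereo_bonds(g$smiles),
    Num_AromaticBonds = if (nrow(bonds)) sum(bonds$aromatic) else 0L,
    Num_AromaticRings = length(g$aromatic_rings),
    Num_StereoAtoms = count_stereo_atoms(g$smiles),
    Num_BridgeBonds = topo$n_bridge_bonds,
    Num_BridgeHeadAtoms = topo$n_bridgehead,
    Num_SpiroAtoms = topo$n_spiro
  )[.molprops_names]
}

ob_props <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))
  ChemmineR::propOB(sdf)
}

#' Compute the 19 molecular property descriptors
#'
#' A fixed block of simple interpretable molecular properties and counts:
#' an atomic-contribution lipophilicity estimate (column `ALogP`),
#' molecular weight, atom/bond/ring/aromaticity counts, hydrogen-bond
#' donor/acceptor counts (three conventions each), stereo counts and
#' ring-fusion topology counts (bridgehead, bridge-bond, spiro).
#'
#' @param smiles a single standardised SMILES string.
#' @return named numeric vector of length 19.
#' @export
compute_molprops <- function(smiles) {
  g <- mol_graph(smiles)
  assert_that(!is.null(g), sprintf("unparsable structure: %s", smiles))
  molprops_from_graph(g, ob_props(smiles)[1, ])
}

# ---- chi connectivity indices -------------------------------------------

.chi_names <- c(
  "Chi0", "Chi1", "Chi2", "Chi3_P", "Chi3_C", "Chi4_P",
  "Chi0_V", "Chi1_V", "Chi2_V", "Chi3_PV", "Chi3_CV", "Chi4_PV"
)

valence_delta <- function(g) {
  zv <- .zv[g$symbol]
  z <- c(B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
    Cl = 17, Br = 35, I = 53)[g$symbol]
  dv <- ifelse(z - zv - 1 > 0, (zv - g$nH) / (z - zv - 1), zv - g$nH)
  pmax(dv, 1e-8)
}

# enumerate simple paths with `len` bonds; each path counted once
simple_paths <- function(g, len) {
  adj <- lapply(seq_len(g$n), function(a) {
    b <- g$bonds
    c(b$a2[b$a1 == a], b$a1[b$a2 == a])
  })
  paths <- list()
  walk <- function(path) {
    if (length(path) == len + 1) {
      if (path[1] < path[length(path)]) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in adj[[path[length(path)]]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  for (a in seq_len(g$n)) walk(a)
  paths
}

chi_from_graph <- function(g) {
  d <- pmax(g$degree, 1)
  dv <- valence_delta(g)
  chi_sum <- function(delta, paths) {
    if (!length(paths)) return(0)
    sum(vapply(paths, function(p) 1 / sqrt(prod(delta[p])), numeric(1)))
  }
  p2 <- simple_paths(g, 2); p3 <- simple_paths(g, 3); p4 <- simple_paths(g, 4)
  # order-3 clusters: star of a degree>=3 centre and 3 of its neighbours
  clusters <- list()
  for (a in which(g$degree >= 3)) {
    nbs <- c(g$bonds$a2[g$bonds$a1 == a], g$bonds$a1[g$bonds$a2 == a])
    cmb <- utils::combn(sort(nbs), 3)
    for (k in seq_len(ncol(cmb))) {
      clusters[[length(clusters) + 1L]] <- c(a, cmb[, k])
    }
  }
  bonds_p <- if (nrow(g$bonds)) {
    lapply(seq_len(nrow(g$bonds)), function(k) c(g$bonds$a1[k], g$bonds$a2[k]))
  } else {
    list()
  }
  vals <- c(
    sum(1 / sqrt(d)), chi_sum(d, bonds_p), chi_sum(d, p2), chi_sum(d, p3),
    chi_sum(d, clusters), chi_sum(d, p4),
    sum(1 / sqrt(dv)), chi_sum(dv, bonds_p), chi_sum(dv, p2),
    chi_sum(dv, p3), chi_sum(dv, clusters), chi_sum(dv, p4)
  )
  stats::setNames(vals, .chi_names)
}

#' Compute Kier-Hall chi connectivity indices
#'
#' Simple and valence molecular connectivity indices of orders 0-2 plus
#' order-3 path, order-3 cluster and order-4 path terms (12 values).
#' Simple indices use heavy-atom graph degrees; valence indices use
#' Kier-Hall valence deltas computed from valence electron counts,
#' attached hydrogens and the principal quantum number.
#'
#' @param smiles a single standardised SMILES string.
#' @return named numeric vector of length 12.
#' @export
compute_chi <- function(smiles) {
  g <- mol_graph(smiles)
  assert_that(!is.null(g), sprintf("unparsable structure: %s", smiles))
  chi_from_graph(g)
}

# ---- E-state -------------------------------------------------------------

# Fixed atom-type alphabet (79 types). Bond-pattern prefix letters in the
# order aromatic, triple, double, single; hydrogen count suffix; p/m for
# formal charge. Types for elements outside the organic parser never fire
# but are part of the fixed declared inventory.
.estate_types <- c(
  "sLi", "ssBe", "sBH2", "ssBH", "sssB", "ssssBm",
  "sCH3", "ssCH2", "sssCH", "ssssC", "dCH2", "dsCH", "dssC",
  "tCH", "tsC", "ddC", "aaCH", "aasC", "aaaC",
  "sNH2", "ssNH", "sssN", "dNH", "dsN", "ddsN", "tN", "aaN", "aaNH",
  "aasN", "sNH3p", "ssNH2p", "sssNHp", "ssssNp",
  "sOH", "ssO", "dO", "aaO", "sOm", "ssOp",
  "sF",
  "sSiH3", "ssSiH2", "sssSiH", "ssssSi",
  "sPH2", "ssPH", "sssP", "dsssP", "sssssP",
  "sSH", "ssS", "dS", "aaS", "dssS", "ddssS", "sSm",
  "sCl",
  "sGeH3", "ssGeH2", "sssGeH", "ssssGe",
  "sssAs", "dsssAs", "sssssAs",
  "sSeH", "dSe", "ssSe", "aaSe", "ddssSe",
  "sBr",
  "sSnH3", "ssSnH2", "sssSnH", "ssssSn",
  "sI",
  "ssssPb", "ssssBe", "ssAsH", "other"
)

.estate_colnames <- c(
  paste0("Estate_S_", .estate_types), paste0("Estate_N_", .estate_types),
  "Estate_S_total", "Estate_S_max", "Estate_S_min"
)

estate_atom_type <- function(g, a) {
  b <- g$bonds
  mine <- which(b$a1 == a | b$a2 == a)
  arom <- sum(b$aromatic[mine])
  trip <- sum(!b$aromatic[mine] & b$order[mine] == 3)
  dbl <- sum(!b$aromatic[mine] & b$order[mine] == 2)
  sng <- sum(!b$aromatic[mine] & b$order[mine] == 1)
  prefix <- paste0(
    strrep("a", arom), strrep("t", trip), strrep("d", dbl), strrep("s", sng)
  )
  h <- if (g$nH[a] == 0) "" else if (g$nH[a] == 1) "H" else paste0("H", g$nH[a])
  chg <- if (g$charge[a] > 0) "p" else if (g$charge[a] < 0) "m" else ""
  key <- paste0(prefix, g$symbol[a], h, chg)
  if (key %in% .estate_types) key else "other"
}

estate_atom_values <- function(g) {
  d <- pmax(g$degree, 1)
  dv_raw <- .zv[g$symbol] - g$nH + g$charge
  pq <- .pqn[g$symbol]
  I <- ((2 / pq)^2 * dv_raw + 1) / d
  r <- g$dist + 1
  S <- I
  for (i in seq_len(g$n)) {
    others <- setdiff(seq_len(g$n), i)
    fin <- others[is.finite(r[i, others])]
    if (length(fin)) S[i] <- I[i] + sum((I[i] - I[fin]) / r[i, fin]^2)
  }
  list(I = I, S = S)
}

estate_from_graph <- function(g) {
  av <- estate_atom_values(g)
  types <- vapply(seq_len(g$n), function(a) estate_atom_type(g, a), character(1))
  sums <- stats::setNames(numeric(length(.estate_types)), .estate_types)
  counts <- stats::setNames(numeric(length(.estate_types)), .estate_types)
  for (i in seq_len(g$n)) {
    sums[types[i]] <- sums[types[i]] + av$S[i]
    counts[types[i]] <- counts[types[i]] + 1
  }
  out <- c(sums, counts, sum(av$S), max(av$S), min(av$S))
  stats::setNames(out, .estate_colnames)
}

#' Compute electrotopological state (E-state) descriptors
#'
#' Per-atom intrinsic states `I = ((2/N)^2 * delta_v + 1) / delta` are
#' perturbed by `(I_i - I_j) / r_ij^2` over all heavy-atom pairs (`r` =
#' topological distance + 1) to give atom E-state values `S`, which are
#' aggregated into sums and counts over a fixed 79-entry atom-type
#' alphabet plus three whole-molecule summaries (total, max, min): 161
#' columns in all. Isolated heavy atoms use the hydrogen-inclusive
#' convention `delta = 1`.
#'
#' @param smiles a single standardised SMILES string.
#' @return named numeric vector of length 161.
#' @export
compute_estate <- function(smiles) {
  g <- mol_graph(smiles)
  assert_that(!is.null(g), sprintf("unparsable structure: %s", smiles))
  estate_from_graph(g)
}

# ---- circular fingerprints ----------------------------------------------

.atomic_number <- c(B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
  S = 16, Cl = 17, Br = 35, I = 53)

fp_initial_invariants <- function(g, functional = FALSE) {
  if (functional) {
    # functional-class typing: donor, acceptor, positive, negative,
    # aromatic, halogen flags packed into one integer
    vapply(seq_len(g$n), function(a) {
      flags <- c(
        g$symbol[a] %in% c("N", "O", "S") && g$nH[a] > 0,   # donor
        g$symbol[a] %in% c("N", "O"),                        # acceptor
        g$charge[a] > 0, g$charge[a] < 0,
        g$aromatic_atom[a],
        g$symbol[a] %in% c("F", "Cl", "Br", "I")
      )
      sum(2^(0:5) * flags) + 1L
    }, numeric(1))
  } else {
    vapply(seq_len(g$n), function(a) {
      hash_ints(c(
        .atomic_number[g$symbol[a]], g$degree[a], g$nH[a],
        g$charge[a] + 8, as.integer(g$aromatic_atom[a])
      ))
    }, numeric(1))
  }
}

fp_identifiers <- function(g, radius, functional = FALSE) {
  ids <- fp_initial_invariants(g, functional)
  if (functional) ids <- vapply(ids, function(x) hash_ints(x), numeric(1))
  all_ids <- ids
  bonds <- g$bonds
  bond_code <- if (nrow(bonds)) ifelse(bonds$aromatic, 4L, bonds$order) else integer()
  nb <- lapply(seq_len(g$n), function(a) {
    k <- which(bonds$a1 == a | bonds$a2 == a)
    other <- ifelse(bonds$a1[k] == a, bonds$a2[k], bonds$a1[k])
    list(atom = other, code = bond_code[k])
  })
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (a in seq_len(g$n)) {
        pairs <- cbind(nb[[a]]$code, ids[nb[[a]]$atom])
        if (nrow(pairs)) {
          ord <- order(pairs[, 1], pairs[, 2])
          pairs <- pairs[ord, , drop = FALSE]
        }
        new_ids[a] <- hash_ints(c(r, ids[a], as.vector(t(pairs))))
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  sort(unique(all_ids))
}

#' Compute a circular fingerprint
#'
#' Morgan-style extended-connectivity fingerprints. `ECFP6` uses
#' radius 3 with structural initial atom invariants (atomic number,
#' degree, hydrogen count, charge, aromaticity); `FCFP4` uses radius 2
#' with functional-class invariants (donor, acceptor, positive, negative,
#' aromatic, halogen flags). Returns the raw identifier set (for
#' similarity and sparse learners) and a folded binary vector of the
#' configured width.
#'
#' @param smiles a single standardised SMILES string.
#' @param kind `"ECFP6"` or `"FCFP4"`.
#' @param fold_width width of the folded vector (default 1024).
#' @return list with `ids` (sorted unique substructure identifiers) and
#'   `folded` (named 0/1 numeric vector of length `fold_width`).
#' @export
compute_fingerprint <- function(smiles, kind = c("ECFP6", "FCFP4"),
                                fold_width = 1024) {
  kind <- match.arg(kind)
  g <- mol_graph(smiles)
  assert_that(!is.null(g), sprintf("unparsable structure: %s", smiles))
  fingerprint_from_graph(g, kind, fold_width)
}

fingerprint_from_graph <- function(g, kind, fold_width) {
  radius <- if (kind == "ECFP6") 3L else 2L
  ids <- fp_identifiers(g, radius, functional = kind == "FCFP4")
  folded <- numeric(fold_width)
  folded[(ids %% fold_width) + 1L] <- 1
  names(folded) <- sprintf("%s_%04d", kind, seq_len(fold_width))
  list(ids = ids, folded = folded)
}

# Tanimoto similarity matrix over a list of identifier sets, via a sparse
# record x identifier indicator matrix.
tanimoto_matrix <- function(id_sets) {
  all_ids <- sort(unique(unlist(id_sets)))
  i <- rep(seq_along(id_sets), lengths(id_sets))
  j <- match(unlist(id_sets), all_ids)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
    dims = c(length(id_sets), length(all_ids)))
  inter <- as.matrix(Matrix::tcrossprod(m))
  sizes <- lengths(id_sets)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 1)
  diag(sim) <- 1
  sim
}

# ---- descriptor set ------------------------------------------------------

#' Descriptor block registry
#'
#' The five available descriptor blocks with their subset-accounting
#' sizes. Fingerprint blocks count as one descriptor in subset accounting
#' but expand to `fold_width` numeric columns for numeric-only learners.
#'
#' @return tibble with columns `name`, `kind`, `size`.
#' @export
descriptor_blocks <- function() {
  tibble(
    name = c("Molprops", "Chi", "Estate", "ECFP6", "FCFP4"),
    kind = c("numeric", "numeric", "numeric", "fingerprint", "fingerprint"),
    size = c(19L, 12L, 161L, 1L, 1L)
  )
}

#' Compute descriptor matrices for a dataset
#'
#' Computes the requested descriptor blocks for every record. Records for
#' which any descriptor computation fails are excluded from the matrices
#' with a logged reason. Fingerprint blocks keep both the raw identifier
#' multiset (similarity, sparse learners) and a folded numeric expansion.
#'
#' @param dataset a standardised `qsar_dataset` (needs `smiles_std`).
#' @param blocks character vector of block names (default: all five).
#' @param fold_width folded width for fingerprint expansion.
#' @return a `descriptor_set`: list with per-block matrices, fingerprint
#'   id sets, record ids, exclusions and provenance.
#' @export
compute_descriptors <- function(dataset, blocks = descriptor_blocks()$name,
                                fold_width = 1024) {
  assert_that(all(blocks %in% descriptor_blocks()$name), "unknown descriptor block")
  rec <- as_tibble(dataset)
  assert_that(all(!is.na(rec$smiles_std)),
    "dataset must be standardised first (smiles_std missing)")
  graphs <- mol_graphs(rec$smiles_std)
  ok <- !vapply(graphs, is.null, logical(1))
  excluded <- tibble(
    record_id = rec$record_id[!ok],
    reason = "descriptor computation failed: unparsable standardised structure"
  )
  rec <- rec[ok, ]; graphs <- graphs[ok]
  ids <- rec$record_id
  out <- list(
    record_ids = ids, blocks = list(), fp_ids = list(), excluded = excluded,
    provenance = list(blocks = blocks, fold_width = fold_width)
  )
  if ("Molprops" %in% blocks) {
    ob <- ob_props(rec$smiles_std)
    m <- t(vapply(seq_along(graphs), function(k)
      molprops_from_graph(graphs[[k]], ob[k, ]), numeric(19)))
    rownames(m) <- ids
    out$blocks$Molprops <- m
  }
  if ("Chi" %in% blocks) {
    m <- t(vapply(graphs, chi_from_graph, numeric(12)))
    rownames(m) <- ids
    out$blocks$Chi <- m
  }
  if ("Estate" %in% blocks) {
    m <- t(vapply(graphs, estate_from_graph, numeric(161)))
    rownames(m) <- ids
    out$blocks$Estate <- m
  }
  for (kind in intersect(c("ECFP6", "FCFP4"), blocks)) {
    fps <- lapply(graphs, fingerprint_from_graph, kind = kind,
      fold_width = fold_width)
    m <- t(vapply(fps, `[[`, numeric(fold_width), "folded"))
    rownames(m) <- ids
    out$blocks[[kind]] <- m
    out$fp_ids[[kind]] <- stats::setNames(lapply(fps, `[[`, "ids"), ids)
  }
  structure(out, class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "<descriptor_set> %d records; blocks: %s (fold width %d)\n",
    length(x$record_ids),
    paste(names(x$blocks), collapse = ", "), x$provenance$fold_width
  ))
  invisible(x)
}

#' Define named descriptor subsets
#'
#' Instantiates descriptor subsets from a configuration mapping subset
#' labels to sets of block names; combination subsets are unions of
#' blocks. Subset size follows block accounting (fingerprints count 1).
#'
#' @param config named list: label -> character vector of block names.
#' @return tibble with columns `label`, `blocks` (list), `size`.
#' @export
make_subsets <- function(config) {
  assert_that(!anyDuplicated(names(config)), "duplicate subset label")
  reg <- descriptor_blocks()
  rows <- purrr::imap(config, function(blocks, label) {
    unknown <- setdiff(blocks, reg$name)
    assert_that(length(unknown) == 0,
      sprintf("unknown block name(s): %s", paste(unknown, collapse = ", ")))
    assert_that(!anyDuplicated(blocks),
      sprintf("duplicate block in subset %s", label))
    sz <- sum(reg$size[match(blocks, reg$name)])
    tibble(label = label, blocks = list(blocks), size = sz)
  })
  dplyr::bind_rows(rows)
}

#' The standard ten descriptor subsets
#'
#' Five single-block subsets and five combination subsets (each block
#' combined with Molprops, and the union of all five blocks).
#'
#' @return tibble as from [make_subsets()].
#' @export
default_subsets <- function() {
  make_subsets(list(
    Chi = "Chi",
    ECFP6 = "ECFP6",
    Estate = "Estate",
    FCFP4 = "FCFP4",
    Molprops = "Molprops",
    Chi_Molprops = c("Chi", "Molprops"),
    ECFP6_Molprops = c("ECFP6", "Molprops"),
    Estate_Molprops = c("Estate", "Molprops"),
    FCFP4_Molprops = c("FCFP4", "Molprops"),
    Chi_ECFP6_Estate_FCFP4_Molprops =
      c("Chi", "ECFP6", "Estate", "FCFP4", "Molprops")
  ))
}

# Assemble the expanded numeric matrix for one subset (fingerprints
# expanded to their folded width), restricted to the given record ids.
subset_matrix <- function(descriptor_set, subset_blocks, record_ids = NULL) {
  missing_blocks <- setdiff(subset_blocks, names(descriptor_set$blocks))
  assert_that(length(missing_blocks) == 0, sprintf(
    "blocks not computed: %s", paste(missing_blocks, collapse = ", ")))
  m <- do.call(cbind, descriptor_set$blocks[subset_blocks])
  if (!is.null(record_ids)) {
    missing_rec <- setdiff(record_ids, rownames(m))
    assert_that(length(missing_rec) == 0, sprintf(
      "descriptor matrix does not cover record(s): %s",
      paste(utils::head(missing_rec, 5), collapse = ", ")))
    m <- m[record_ids, , drop = FALSE]
  }
  m
}
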