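# Molecular graph construction.
#
# SMILES parsing and canonicalisation are delegated to OpenBabel via
# ChemmineR/ChemmineOB; everything downstream (implicit hydrogens, ring
# perception, a simplified Hueckel aromaticity model, topological distances)
# is computed on the heavy-atom graph returned here. All descriptor engines
# consume this one representation.

# default valences used for implicit-hydrogen assignment
.base_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

# principal quantum number per element (E-state intrinsic states)
.pqn <- c(
  B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3,
  Cl = 3, Br = 4, I = 5
)

# valence electron counts
.zv <- c(
  B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6,
  Cl = 7, Br = 7, I = 7
)

#' Canonicalise SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Unparsable inputs yield
#' `NA` rather than an error so callers can exclude and report them.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
      error = function(e) ""
    )
    out <- sub("\t.*$", "", sub("[\r\n]+$", "", out))
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into a molecular graph, or NULL when unparsable.
mol_graph <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) return(NULL)
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  symbol <- sub("_.*$", "", rownames(ab))
  if (!all(symbol %in% names(.base_valence))) return(NULL)
  chg_col <- if ("C6" %in% colnames(ab)) "C6" else 5
  code <- ab[, chg_col]
  charge <- ifelse(code == 0, 0, 4 - code)
  n <- length(symbol)

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- tibble(
      a1 = pmin(as.integer(bb[, 1]), as.integer(bb[, 2])),
      a2 = pmax(as.integer(bb[, 1]), as.integer(bb[, 2])),
      order = as.integer(bb[, 3])
    )
  }

  # implicit hydrogens from default valences adjusted for formal charge
  bosum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    bosum[bonds$a1[k]] <- bosum[bonds$a1[k]] + bonds$order[k]
    bosum[bonds$a2[k]] <- bosum[bonds$a2[k]] + bonds$order[k]
  }
  base <- .base_valence[symbol]
  val <- ifelse(symbol %in% c("N", "O", "P", "S"), base + charge,
    base - abs(charge)
  )
  # hypervalent S/P: bump valence in steps of 2 when bond orders exceed it
  over <- bosum > val & symbol %in% c("S", "P")
  val[over] <- val[over] + 2 * ceiling((bosum[over] - val[over]) / 2)
  nH <- pmax(0, round(val - bosum))

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0) {
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  }
  degree <- as.integer(igraph::degree(g))
  dist <- igraph::distances(g)

  rings <- perceive_rings(g, bonds)
  ring_info <- flag_aromatic(symbol, bonds, rings)

  list(
    smiles = smiles, n = n, symbol = symbol, charge = as.numeric(charge),
    nH = as.numeric(nH), degree = degree, bonds = ring_info$bonds,
    dist = dist, rings = rings, aromatic_atom = ring_info$aromatic_atom,
    aromatic_rings = ring_info$aromatic_rings, graph = g
  )
}

# Smallest ring through every cyclic edge (deduplicated) -- a practical
# stand-in for SSSR adequate for ring counts and fusion topology of
# ordinary organic molecules.
perceive_rings <- function(g, bonds) {
  if (nrow(bonds) == 0 || igraph::ecount(g) == 0) return(list())
  bridge_ids <- tryCatch(as.integer(igraph::bridges(g)), error = function(e) integer())
  rings <- list()
  seen <- character()
  for (eid in seq_len(igraph::ecount(g))) {
    if (eid %in% bridge_ids) next
    ends <- igraph::ends(g, eid)
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = ends[1], to = ends[2])$vpath[[1]])
    if (length(sp) < 2) next
    ring <- sort(as.integer(sp))
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- as.integer(sp)
    }
  }
  rings
}

# Simplified Hueckel model: 5/6-rings where every member is sp2-capable and
# pi electrons total 6. Covers benzenoid rings, pyridine-type N, and
# pyrrole/furan/thiophene-type heteroatoms.
flag_aromatic <- function(symbol, bonds, rings) {
  n <- length(symbol)
  has_double_to <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] == 2) {
      has_double_to[[bonds$a1[k]]] <- c(has_double_to[[bonds$a1[k]]], bonds$a2[k])
      has_double_to[[bonds$a2[k]]] <- c(has_double_to[[bonds$a2[k]]], bonds$a1[k])
    }
  }
  ring_atoms <- unique(unlist(rings))
  aromatic_ring <- logical(length(rings))
  for (ri in seq_along(rings)) {
    ring <- rings[[ri]]
    if (!length(ring) %in% c(5L, 6L)) next
    pi <- 0; ok <- TRUE
    for (a in ring) {
      dbl <- intersect(has_double_to[[a]], ring_atoms)
      if (length(dbl) > 0) {
        pi <- pi + 1
      } else if (symbol[a] %in% c("N", "O", "S")) {
        pi <- pi + 2
      } else {
        ok <- FALSE; break
      }
    }
    aromatic_ring[ri] <- ok && pi == 6
  }
  aromatic_atom <- rep(FALSE, n)
  for (ri in which(aromatic_ring)) aromatic_atom[rings[[ri]]] <- TRUE
  in_ring <- rep(FALSE, nrow(bonds))
  arom_bond <- rep(FALSE, nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    for (ri in seq_along(rings)) {
      ring <- rings[[ri]]
      if (bonds$a1[k] %in% ring && bonds$a2[k] %in% ring) {
        in_ring[k] <- TRUE
        if (aromatic_ring[ri]) arom_bond[k] <- TRUE
      }
    }
  }
  bonds$in_ring <- in_ring
  bonds$aromatic <- arom_bond
  list(
    bonds = bonds, aromatic_atom = aromatic_atom,
    aromatic_rings = rings[aromatic_ring]
  )
}

# Parse a vector of SMILES; returns a list (NULL entries for failures).
mol_graphs <- function(smiles) {
  lapply(smiles, mol_graph)
}
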