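# Synthetic structure-activity datasets with planted, tunable signal.
#
# Molecules are assembled from a built-in fragment grammar (aromatic and
# aliphatic scaffolds x substituents). Classification sets plant a
# sulfonamide pharmacophore (-S(=O)(=O)N) whose presence determines the
# label before noise; regression sets derive the response from a linear
# combination of computed lipophilicity and ring count plus Gaussian
# noise. A configurable fraction of records is emitted as salt forms so
# desalting (and, for amine hydrochlorides, neutralisation) is exercised
# end to end.

.scaffolds_mono <- c(
  "c1ccc(%s)cc1", "c1ccc(%s)nc1", "c1cc(%s)oc1", "c1cc(%s)sc1",
  "C1CCC(%s)CC1", "C1CCC(%s)C1", "c1ccc2cc(%s)ccc2c1", "C(%s)CCO"
)
.scaffolds_di <- c(
  "c1cc(%s)cc(%s)c1", "c1ccc(%s)c(%s)c1", "C1CC(%s)CC(%s)C1",
  "c1cc(%s)ccc1O%s"
)
.scaffolds_tri <- c(
  "c1c(%s)cc(%s)cc1%s", "C(%s)(%s)CC%s"
)

.substituents <- c(
  "C", "CC", "CCC", "C(C)C", "CCCC", "C(C)(C)C", "C=C", "CC=C",
  "O", "OC", "OCC", "CO", "CCO", "N", "NC", "N(C)C", "CN", "CCN",
  "C(=O)O", "CC(=O)O", "C(=O)N", "C(=O)OC", "C#N", "C(F)(F)F",
  "F", "Cl", "Br", "[N+](=O)[O-]", "S", "SC"
)

.pharmacophore <- "S(=O)(=O)N"

assemble_molecule <- function(rng_draws, with_pharmacophore = FALSE) {
  # rng_draws: list(kind, scaffold, subs) already sampled by the caller
  kind <- rng_draws$kind
  tmpl <- switch(kind,
    mono = .scaffolds_mono[rng_draws$scaffold],
    di = .scaffolds_di[rng_draws$scaffold],
    tri = .scaffolds_tri[rng_draws$scaffold]
  )
  subs <- .substituents[rng_draws$subs]
  if (with_pharmacophore) subs[1] <- .pharmacophore
  do.call(sprintf, c(list(tmpl), as.list(subs)))
}

draw_molecule_spec <- function() {
  u <- stats::runif(1)
  if (u < 0.10) {
    list(kind = "mono", scaffold = sample.int(length(.scaffolds_mono), 1),
      subs = sample.int(length(.substituents), 1))
  } else if (u < 0.55) {
    list(kind = "di", scaffold = sample.int(length(.scaffolds_di), 1),
      subs = sample.int(length(.substituents), 2, replace = TRUE))
  } else {
    list(kind = "tri", scaffold = sample.int(length(.scaffolds_tri), 1),
      subs = sample.int(length(.substituents), 3, replace = TRUE))
  }
}

#' Generate synthetic molecules
#'
#' Draws valid, standardisable SMILES from the built-in fragment grammar.
#' Duplicates are allowed but rare (below 5 percent for n up to 1000).
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed; identical seeds give identical lists.
#' @return character vector of SMILES.
#' @export
generate_molecules <- function(n, seed = 1) {
  assert_that(n >= 1, "n must be at least 1")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) assemble_molecule(draw_molecule_spec()),
      character(1))
  })
}

salt_form <- function(smiles) {
  # amine-bearing molecules become hydrochloride ion pairs (exercises
  # desalting and neutralisation); others get a neutral HCl companion
  if (grepl("(?<![#=\\[])N$", smiles, perl = TRUE) || grepl("(N)", smiles, fixed = TRUE)) {
    paste0(sub("(N)", "([NH3+])", sub("(?<![#=\\[])N$", "[NH3+]", smiles, perl = TRUE),
      fixed = TRUE), ".[Cl-]")
  } else {
    paste0(smiles, ".Cl")
  }
}

#' Generate a synthetic classification dataset
#'
#' Plants the sulfonamide pharmacophore in a `class_balance` fraction of
#' the records; the label is positive iff the pharmacophore is present,
#' then flipped with probability `noise`. The achieved positive fraction
#' stays within 0.05 of `class_balance` for n >= 200.
#'
#' @param n_records number of records.
#' @param seed integer seed.
#' @param noise label-flip probability in [0, 1].
#' @param class_balance target positive fraction.
#' @param salt_fraction fraction of records emitted as salt forms.
#' @return a categorical `qsar_dataset` (labels `active`/`inactive`,
#'   positive class `active`); the planted truth is kept in
#'   `attr(x, "generator")`.
#' @export
generate_classification_set <- function(n_records, seed = 1, noise = 0.1,
                                        class_balance = 0.5,
                                        salt_fraction = 0.1) {
  assert_that(n_records >= 2, "need at least 2 records")
  assert_that(class_balance > 0 && class_balance < 1,
    "class_balance must be in (0, 1)")
  n_pos <- round(n_records * class_balance)
  assert_that(n_pos >= 1 && n_pos <= n_records - 1,
    "class_balance unreachable at this n")
  withr::with_seed(seed, {
    has_pharma <- sample(rep(c(TRUE, FALSE), c(n_pos, n_records - n_pos)))
    smiles <- vapply(seq_len(n_records), function(i)
      assemble_molecule(draw_molecule_spec(), with_pharmacophore = has_pharma[i]),
      character(1))
    label <- ifelse(has_pharma, "active", "inactive")
    flip <- stats::runif(n_records) < noise
    label[flip] <- ifelse(label[flip] == "active", "inactive", "active")
    is_salt <- stats::runif(n_records) < salt_fraction
    smiles[is_salt] <- vapply(smiles[is_salt], salt_form, character(1))
  })
  rec <- tibble(
    record_id = sprintf("mol%04d", seq_len(n_records)),
    smiles_raw = smiles, smiles_std = NA_character_,
    response_raw = label, response = label
  )
  out <- new_qsar_dataset(rec, "categorical", positive_class = "active",
    label_set = c("active", "inactive"))
  attr(out, "generator") <- list(task = "classification", seed = seed,
    noise = noise, class_balance = class_balance,
    salt_fraction = salt_fraction, has_pharmacophore = has_pharma)
  out
}

#' Generate a synthetic regression dataset
#'
#' The response is `1.2 * logP + 0.8 * ring_count + noise` with
#' lipophilicity and ring count computed from the generated structure
#' and Gaussian noise of the configured standard deviation; the
#' generating coefficients are recorded in `attr(x, "generator")` for
#' recovery tests.
#'
#' @param n_records number of records.
#' @param seed integer seed.
#' @param noise_sd Gaussian noise standard deviation on the response.
#' @param salt_fraction fraction of records emitted as salt forms.
#' @return a continuous `qsar_dataset`.
#' @export
generate_regression_set <- function(n_records, seed = 1, noise_sd = 0.5,
                                    salt_fraction = 0.1) {
  assert_that(n_records >= 2, "need at least 2 records")
  withr::with_seed(seed, {
    smiles <- vapply(seq_len(n_records), function(i)
      assemble_molecule(draw_molecule_spec()), character(1))
    eps <- stats::rnorm(n_records, 0, noise_sd)
    is_salt <- stats::runif(n_records) < salt_fraction
  })
  # signal computed on the clean (pre-salt) structure
  ob <- ob_props(smiles)
  graphs <- mol_graphs(smiles)
  ring_count <- vapply(graphs, function(g)
    nrow(g$bonds) - g$n + igraph::components(g$graph)$no, numeric(1))
  coef <- c(logP = 1.2, ring_count = 0.8)
  y <- coef["logP"] * as.numeric(ob$logP) + coef["ring_count"] * ring_count + eps
  smiles[is_salt] <- vapply(smiles[is_salt], salt_form, character(1))
  rec <- tibble(
    record_id = sprintf("mol%04d", seq_len(n_records)),
    smiles_raw = smiles, smiles_std = NA_character_,
    response_raw = as.numeric(y), response = as.numeric(y)
  )
  out <- new_qsar_dataset(rec, "continuous")
  attr(out, "generator") <- list(task = "regression", seed = seed,
    noise_sd = noise_sd, coefficients = coef, salt_fraction = salt_fraction,
    signal = y - eps)
  out
}
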