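# Dataset container and chemistry/response preparation.
#
# A qsar_dataset is a tibble of molecule records (record_id, smiles_raw,
# smiles_std, response_raw, response) carrying the preparation state in
# attributes: endpoint_type, positive_class, prep_spec (the ordered list of
# applied steps with fitted constants, replayable at prediction time),
# prep_log, excluded (records dropped with reasons) and load_report.

new_qsar_dataset <- function(records, endpoint_type,
                             positive_class = NULL, label_set = NULL,
                             prep_spec = list(), prep_log = character(),
                             excluded = NULL, load_report = list()) {
  assert_that(endpoint_type %in% c("continuous", "categorical"),
    "endpoint_type must be 'continuous' or 'categorical'")
  assert_that(!anyDuplicated(records$record_id),
    "record_id must be unique within a dataset")
  out <- as_tibble(records)
  class(out) <- c("qsar_dataset", class(out))
  attr(out, "endpoint_type") <- endpoint_type
  attr(out, "positive_class") <- positive_class
  attr(out, "label_set") <- label_set
  attr(out, "prep_spec") <- prep_spec
  attr(out, "prep_log") <- prep_log
  attr(out, "excluded") <- excluded %||%
    tibble(record_id = character(), reason = character())
  attr(out, "load_report") <- load_report
  out
}

dataset_meta <- function(dataset) {
  list(
    endpoint_type = attr(dataset, "endpoint_type"),
    positive_class = attr(dataset, "positive_class"),
    label_set = attr(dataset, "label_set"),
    prep_spec = attr(dataset, "prep_spec"),
    prep_log = attr(dataset, "prep_log"),
    excluded = attr(dataset, "excluded"),
    load_report = attr(dataset, "load_report")
  )
}

with_meta <- function(records, meta) {
  new_qsar_dataset(records, meta$endpoint_type, meta$positive_class,
    meta$label_set, meta$prep_spec, meta$prep_log, meta$excluded,
    meta$load_report)
}

#' Endpoint type of a dataset
#' @param dataset a `qsar_dataset`.
#' @return `"continuous"` or `"categorical"`.
#' @export
endpoint_type <- function(dataset) attr(dataset, "endpoint_type")

#' Preparation specification of a dataset
#'
#' The ordered list of preparation steps applied so far, including any
#' constants fitted on the data (scaling centres, category maps). Replaying
#' this spec on the raw records reproduces the prepared dataset exactly;
#' published models carry it so predictions replay identical preparation.
#'
#' @param dataset a `qsar_dataset`.
#' @return list of steps, each `list(name = , params = )`.
#' @export
prep_spec <- function(dataset) attr(dataset, "prep_spec")

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf(
    "<qsar_dataset> %d records, endpoint = %s%s\n", nrow(x),
    endpoint_type(x),
    if (!is.null(attr(x, "positive_class")))
      paste0(", positive class = ", attr(x, "positive_class")) else ""
  ))
  lg <- attr(x, "prep_log")
  if (length(lg)) cat("prep:", paste(lg, collapse = " -> "), "\n")
  ex <- attr(x, "excluded")
  if (nrow(ex)) cat(sprintf("excluded: %d record(s)\n", nrow(ex)))
  NextMethod()
}

#' Read a structure-activity dataset
#'
#' Reads SMILES+CSV (columns `id`, `smiles`, and the response column) or an
#' SDF (response taken from a named data tag). Records whose structure does
#' not parse or whose response is missing are excluded and counted in the
#' load report (`attr(x, "load_report")`).
#'
#' @param path input file.
#' @param format `"smiles_csv"` or `"sdf"`.
#' @param response_field name of the response column (CSV) or tag (SDF).
#' @param endpoint_type `"continuous"` or `"categorical"`.
#' @param positive_class for categorical endpoints, the positive label.
#' @return a `qsar_dataset` of the parsable records.
#' @export
read_dataset <- function(path, format = c("smiles_csv", "sdf"),
                         response_field = "response",
                         endpoint_type = c("continuous", "categorical"),
                         positive_class = NULL) {
  format <- match.arg(format)
  endpoint_type <- match.arg(endpoint_type)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "smiles_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    assert_that(all(c("id", "smiles") %in% names(raw)),
      "smiles_csv requires columns 'id' and 'smiles'")
    assert_that(response_field %in% names(raw),
      sprintf("response column '%s' not found", response_field))
    rec <- tibble(
      record_id = as.character(raw$id),
      smiles_raw = as.character(raw$smiles),
      response_raw = raw[[response_field]]
    )
  } else {
    sdfs <- ChemmineR::read.SDFset(path)
    smi <- tryCatch(
      as.character(ChemmineR::sdf2smiles(sdfs)),
      error = function(e) rep(NA_character_, length(sdfs))
    )
    db <- ChemmineR::datablock(sdfs)
    resp <- vapply(db, function(d) {
      if (response_field %in% names(d)) d[[response_field]] else NA_character_
    }, character(1))
    ids <- ChemmineR::sdfid(sdfs)
    ids[!nzchar(ids) | is.na(ids)] <- paste0("mol_", which(!nzchar(ids) | is.na(ids)))
    rec <- tibble(
      record_id = make.unique(as.character(ids)),
      smiles_raw = smi, response_raw = resp
    )
  }
  if (endpoint_type == "continuous") {
    rec$response_raw <- suppressWarnings(as.numeric(rec$response_raw))
  } else {
    rec$response_raw <- as.character(rec$response_raw)
    rec$response_raw[!is.na(rec$response_raw) & !nzchar(rec$response_raw)] <- NA
  }
  missing_resp <- is.na(rec$response_raw)
  canon <- canonical_smiles(rec$smiles_raw)
  bad_structure <- is.na(canon) & !missing_resp
  keep <- !missing_resp & !bad_structure
  excluded <- tibble(
    record_id = rec$record_id[!keep],
    reason = ifelse(missing_resp[!keep], "missing response", "unparsable structure")
  )
  rec <- rec[keep, ]
  assert_that(nrow(rec) > 0, "zero parsable records")
  rec$smiles_std <- NA_character_
  rec$response <- rec$response_raw
  new_qsar_dataset(
    rec[, c("record_id", "smiles_raw", "smiles_std", "response_raw", "response")],
    endpoint_type,
    positive_class = positive_class,
    label_set = if (endpoint_type == "categorical") sort(unique(rec$response_raw)),
    load_report = list(
      n_read = length(keep), n_kept = sum(keep), n_excluded = sum(!keep),
      reasons = table(excluded$reason)
    ),
    excluded = excluded
  )
}

# ---- chemistry standardisation ------------------------------------------

split_fragments <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

fragment_mw <- function(g) {
  masses <- c(
    B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
    Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Br = 79.904,
    I = 126.904
  )
  sum(masses[g$symbol]) + sum(g$nH) * 1.008
}

# Largest-fragment desalting. A fragment is selectable when it parses under
# the organic element model and is not a bare single-atom ion/solvent
# heteroatom. Ties: heavy-atom count, then MW (descending), then canonical
# string (ascending).
desalt_smiles <- function(smiles) {
  frags <- split_fragments(smiles)
  if (length(frags) == 1) return(frags)
  info <- lapply(frags, function(f) {
    g <- mol_graph(f)
    if (is.null(g)) return(NULL)
    selectable <- g$n >= 2 || (g$charge[1] == 0 && g$symbol[1] == "C")
    if (!selectable) return(NULL)
    list(frag = f, n_heavy = g$n, mw = fragment_mw(g),
      canon = canonical_smiles(f))
  })
  info <- info[!vapply(info, is.null, logical(1))]
  if (length(info) == 0) return(NA_character_)
  ord <- order(
    -vapply(info, `[[`, numeric(1), "n_heavy"),
    -vapply(info, `[[`, numeric(1), "mw"),
    vapply(info, `[[`, character(1), "canon")
  )
  info[[ord[1]]]$frag
}

# Fixed neutralisation rule list: protonate carboxylates/alkoxides/
# thiolates (O-, S- -> OH, SH) except nitro/N-oxide oxygens, deprotonate
# ammonium-type cations carrying at least one hydrogen. Quaternary ammonium
# and zwitterionic nitro groups are left untouched.
neutralize_smiles <- function(smiles) {
  s <- smiles
  # protect nitro / N-oxide patterns
  s <- gsub("[N+](=O)[O-]", "\001", s, fixed = TRUE)
  s <- gsub("[O-][N+](=O)", "\002", s, fixed = TRUE)
  s <- gsub("[n+][O-]", "\003", s, fixed = TRUE)
  s <- gsub("[O-]", "O", s, fixed = TRUE)
  s <- gsub("[S-]", "S", s, fixed = TRUE)
  s <- gsub("[NH4+]", "N", s, fixed = TRUE)
  s <- gsub("[NH3+]", "N", s, fixed = TRUE)
  s <- gsub("[NH2+]", "N", s, fixed = TRUE)
  s <- gsub("[NH+]", "N", s, fixed = TRUE)
  s <- gsub("[nH+]", "n", s, fixed = TRUE)
  s <- gsub("\001", "[N+](=O)[O-]", s, fixed = TRUE)
  s <- gsub("\002", "[O-][N+](=O)", s, fixed = TRUE)
  s <- gsub("\003", "[n+][O-]", s, fixed = TRUE)
  s
}

#' Standardise chemistry
#'
#' Applies an ordered list of chemistry rules to every record and sets
#' `smiles_std`. Available rules: `desalt` (keep the fragment with most
#' heavy atoms; ties by descending molecular weight, then canonical string),
#' `neutralize` (fixed rule list: protonate carboxylates/alkoxides,
#' deprotonate ammonium-type cations; nitro groups preserved) and
#' `canonicalize` (OpenBabel canonical SMILES; always applied last).
#' Records that vanish under desalting (pure salts) or fail to
#' canonicalise are excluded with a logged reason.
#'
#' @param dataset a `qsar_dataset`.
#' @param rules character vector, subset of
#'   `c("desalt", "neutralize", "canonicalize")`, in application order.
#' @return the dataset with `smiles_std` filled in and `prep_log` extended.
#' @export
standardize <- function(dataset, rules = c("desalt", "neutralize", "canonicalize")) {
  assert_that(length(rules) > 0, "rules must be non-empty")
  assert_that(all(rules %in% c("desalt", "neutralize", "canonicalize")),
    "unknown standardisation rule")
  if (!"canonicalize" %in% rules) rules <- c(rules, "canonicalize")
  meta <- dataset_meta(dataset)
  rec <- as_tibble(dataset)
  smi <- rec$smiles_raw
  reason <- rep(NA_character_, length(smi))
  for (rule in rules) {
    if (rule == "desalt") {
      smi <- vapply(smi, function(s) {
        if (is.na(s)) return(NA_character_)
        desalt_smiles(s)
      }, character(1), USE.NAMES = FALSE)
      reason[is.na(smi) & is.na(reason)] <- "desalting removed all fragments"
    } else if (rule == "neutralize") {
      smi <- ifelse(is.na(smi), smi, neutralize_smiles(smi))
    } else {
      out <- canonical_smiles(ifelse(is.na(smi), "", smi))
      reason[is.na(out) & is.na(reason)] <- "failed to canonicalise"
      smi <- out
    }
  }
  keep <- !is.na(smi)
  excluded <- dplyr::bind_rows(
    meta$excluded,
    tibble(record_id = rec$record_id[!keep], reason = reason[!keep])
  )
  rec <- rec[keep, ]
  rec$smiles_std <- smi[keep]
  assert_that(nrow(rec) > 0, "no records survived standardisation")
  meta$excluded <- excluded
  meta$prep_spec <- c(meta$prep_spec, lapply(rules, function(r)
    list(name = r, params = list())))
  meta$prep_log <- c(meta$prep_log, rules)
  with_meta(rec, meta)
}

# ---- response preparation ------------------------------------------------

#' Transform a continuous response
#'
#' `log10` requires strictly positive responses; `unit_variance` centres
#' and scales to unit sample standard deviation and stores the fitted
#' centre/scale in the prep spec so replay on new data reuses the training
#' constants.
#'
#' @param dataset a continuous-endpoint `qsar_dataset`.
#' @param transform `"identity"`, `"log10"` or `"unit_variance"`.
#' @return the dataset with `response` transformed.
#' @export
transform_response <- function(dataset,
                               transform = c("identity", "log10", "unit_variance")) {
  transform <- match.arg(transform)
  assert_that(endpoint_type(dataset) == "continuous",
    "transform_response requires a continuous endpoint")
  meta <- dataset_meta(dataset)
  rec <- as_tibble(dataset)
  y <- as.numeric(rec$response_raw)
  params <- list()
  if (transform == "log10") {
    bad <- which(y <= 0)
    assert_that(length(bad) == 0, sprintf(
      "log10 transform requires positive responses; offending record(s): %s",
      paste(rec$record_id[bad], collapse = ", ")))
    y <- log10(y)
  } else if (transform == "unit_variance") {
    params <- list(center = mean(y), scale = stats::sd(y))
    assert_that(params$scale > 0, "zero response variance; cannot scale")
    y <- (y - params$center) / params$scale
  }
  rec$response <- y
  meta$prep_spec <- c(meta$prep_spec,
    list(list(name = transform, params = params)))
  meta$prep_log <- c(meta$prep_log, transform)
  with_meta(rec, meta)
}

#' Categorise a response
#'
#' Converts the response to categorical, either by a named category map
#' (raw label -> class) or by a strictly increasing threshold list applied
#' to a continuous response. Threshold boundaries go to the upper class
#' (half-open intervals, lower-inclusive at the bottom bin).
#'
#' @param dataset a `qsar_dataset`.
#' @param mapping named character vector (category map) or `NULL`.
#' @param thresholds numeric, strictly increasing; used with `labels`.
#' @param labels class labels for threshold bins (`length(thresholds) + 1`).
#' @param positive_class optional positive class label.
#' @return a categorical `qsar_dataset`; the mapping is stored in the
#'   prep spec.
#' @export
categorize_response <- function(dataset, mapping = NULL, thresholds = NULL,
                                labels = NULL, positive_class = NULL) {
  meta <- dataset_meta(dataset)
  rec <- as_tibble(dataset)
  if (!is.null(mapping)) {
    raw <- as.character(rec$response_raw)
    unmapped <- setdiff(unique(raw), names(mapping))
    assert_that(length(unmapped) == 0, sprintf(
      "unmapped raw label(s): %s", paste(unmapped, collapse = ", ")))
    rec$response <- unname(mapping[raw])
    params <- list(kind = "map", map = as.list(mapping))
  } else {
    assert_that(!is.null(thresholds), "supply a mapping or thresholds")
    assert_that(all(diff(thresholds) > 0), "thresholds must be strictly increasing")
    labels <- labels %||% paste0("class_", seq_len(length(thresholds) + 1))
    assert_that(length(labels) == length(thresholds) + 1,
      "need one more label than thresholds")
    y <- as.numeric(rec$response)
    # boundary values go to the upper class
    bin <- findInterval(y, thresholds, left.open = FALSE) + 1L
    rec$response <- labels[bin]
    params <- list(kind = "thresholds", thresholds = thresholds, labels = labels)
  }
  meta$endpoint_type <- "categorical"
  meta$label_set <- sort(unique(rec$response))
  if (!is.null(positive_class)) {
    assert_that(positive_class %in% meta$label_set,
      "positive_class not in the mapped label set")
    meta$positive_class <- positive_class
  }
  meta$prep_spec <- c(meta$prep_spec,
    list(list(name = "categorize", params = params)))
  meta$prep_log <- c(meta$prep_log, "categorize")
  with_meta(rec, meta)
}

# ---- replay --------------------------------------------------------------

# Replay a prep_spec on raw structures (and optionally raw responses).
# Chemistry steps always replay; response steps replay only when a
# response is supplied. unit_variance replays with the stored training
# constants. Returns a tibble with smiles_std (NA where preparation
# failed) and, when responses given, the transformed response.
replay_prep <- function(spec, smiles_raw, response_raw = NULL) {
  smi <- smiles_raw
  reason <- rep(NA_character_, length(smi))
  y <- response_raw
  for (step in spec) {
    nm <- step$name
    if (nm == "desalt") {
      smi <- vapply(smi, function(s)
        if (is.na(s)) NA_character_ else desalt_smiles(s),
        character(1), USE.NAMES = FALSE)
      reason[is.na(smi) & is.na(reason)] <- "desalting removed all fragments"
    } else if (nm == "neutralize") {
      smi <- ifelse(is.na(smi), smi, neutralize_smiles(smi))
    } else if (nm == "canonicalize") {
      out <- canonical_smiles(ifelse(is.na(smi), "", smi))
      reason[is.na(out) & is.na(reason)] <- "failed to canonicalise"
      smi <- out
    } else if (!is.null(y)) {
      if (nm == "log10") {
        y <- suppressWarnings(log10(as.numeric(y)))
      } else if (nm == "unit_variance") {
        y <- (as.numeric(y) - step$params$center) / step$params$scale
      } else if (nm == "categorize") {
        if (step$params$kind == "map") {
          y <- unname(unlist(step$params$map)[as.character(y)])
        } else {
          bin <- findInterval(as.numeric(y), step$params$thresholds) + 1L
          y <- step$params$labels[bin]
        }
      }
    }
  }
  out <- tibble(smiles_std = smi, fail_reason = reason)
  if (!is.null(response_raw)) out$response <- y
  out
}
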