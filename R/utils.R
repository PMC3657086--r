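#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# 32-bit FNV-1a style hash over a vector of non-negative integers.
# All arithmetic exact in doubles (< 2^53), reduced mod 2^31 so results are
# valid R integers. Deterministic across platforms.
hash_ints <- function(v) {
  h <- 2166136261 %% 2^31
  for (x in v) {
    h <- bitwXor(as.integer(h), as.integer(abs(x) %% 2^31))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

hash_string <- function(s) {
  hash_ints(utf8ToInt(paste(s, collapse = "\x1f")))
}

# Stable hex id from an arbitrary (list) object via its deparsed form.
stable_id <- function(x) {
  sprintf("%08x", hash_string(paste(deparse(x), collapse = " ")))
}

# Derive a child seed from a parent seed and a character tag; keeps results
# below 2^31 so they are valid `set.seed()` inputs.
derive_seed <- function(seed, tag) {
  hash_ints(c(as.integer(seed %% 2^31), utf8ToInt(as.character(tag))))
}

`%||%` <- rlang::`%||%`

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
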