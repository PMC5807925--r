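# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, leaving the
# caller's RNG untouched. All exported stochastic functions funnel through
# this so results are reproducible per seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a stream of sub-seeds from a master seed; keeps every derived seed
# inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical unordered pair key: ids sorted under the fixed total ordering
# (base R string order), joined for joins/lookups.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# All unordered OTU pairs (otu_a < otu_b) for an id vector, as a tibble.
all_pairs <- function(ids) {
  ids <- sort(ids)
  if (length(ids) < 2) {
    return(tibble(otu_a = character(), otu_b = character()))
  }
  idx <- combn(length(ids), 2)
  tibble(otu_a = ids[idx[1, ]], otu_b = ids[idx[2, ]])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
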