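#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic entry points in the package go
# through this so that a seed argument fully determines their output
# without clobbering the user's random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic derivation of sub-seeds from a master seed: a small linear
# congruential step keeps everything inside 32-bit integer range whatever
# the master seed is.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, lo = 0, hi = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= lo && x <= hi
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# lexicographically stable top-k by decreasing value; ties broken by id order
top_k_by_variance <- function(values, ids, k) {
  stopifnot(length(values) == length(ids))
  ord <- order(-values, ids)
  ids[ord[seq_len(min(k, length(ids)))]]
}
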