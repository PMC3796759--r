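# Internal helpers shared across modules.

#' @importFrom stats rnorm runif sd lm coef
NULL

# Deterministic child seed from a parent seed and an index, kept well inside
# the 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629L)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_synergy <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "synergystab_error")))
}

# All-permutations of 1..n in lexicographic order (n is the number of
# synergies, so tiny; exhaustive search is exact and deterministic).
permutations_lex <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_lex(n - 1L)
    base <- setdiff(seq_len(n), i)
    for (p in rest) out[[length(out) + 1L]] <- c(i, base[p])
  }
  out
}
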