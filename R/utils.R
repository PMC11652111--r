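# Shared internal helpers.

# Round half away from zero (printed summary tables use half-up, which base
# round() does not guarantee under IEEE round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Seed handling: run `expr` under a local RNG state seeded with `seed`.
# A NULL seed draws one from the current RNG and reports it, so library use
# without an explicit seed is still reproducible after the fact.
with_seed_reported <- function(seed, expr) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    inform(paste0("No seed supplied; drew seed ", seed))
  }
  seed <- as.integer(seed)
  list(value = withr::with_seed(seed, expr), seed = seed)
}

# Derive a child seed from a base seed and an index, staying inside 32-bit
# integer range. Used so per-belt / per-mountain computations are independent
# of evaluation order.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 104729) %% 2147483647)
}

is_count_vector <- function(y, tol = 1e-8) {
  all(is.finite(y)) && all(y >= 0) && all(abs(y - round(y)) < tol)
}
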