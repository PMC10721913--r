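# Internal helpers: deterministic seed derivation and scoped RNG.

# Combine a master seed with stream indices into a new 31-bit seed.
# Linear-congruential mixing; all intermediates stay below 2^53 so the
# arithmetic is exact in doubles, and the result is a valid set.seed() input.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (a in idx) {
    s <- (s * 69069 + as.double(a) * 12345 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- rlang::`%||%`

stop_eegmvpa <- function(msg, class = "eegmvpa_error") {
  rlang::abort(msg, class = class)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
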