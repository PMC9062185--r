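# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic code in the package goes through
# this so that every output is a pure function of its arguments and seed.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Strictly-upper-triangle vectorization of a square matrix (diagonal
# excluded), column-major order. The common currency of FC comparison.
upper_tri_vec <- function(m) m[upper.tri(m, diag = FALSE)]

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) abort(sprintf("`%s` must be > %g", name, lower))
  if (!strict && x < lower) abort(sprintf("`%s` must be >= %g", name, lower))
  invisible(x)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

# Derive a child seed from a base seed, keeping the result a valid 32-bit
# integer regardless of the inputs.
derive_seed <- function(base, offset) {
  as.integer((as.double(base) + as.double(offset)) %% 2147483647)
}
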