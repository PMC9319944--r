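# Internal helpers shared across modules.

# Deterministic sub-seed derivation so that one user-facing seed can drive
# several independent random channels. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + 7919 * as.double(offset)) %%
               2147483629) + 1L
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  if (nonneg && x < 0)
    abort(sprintf("`%s` must be >= 0 (got %g).", name, x))
  invisible(x)
}

check_increasing <- function(x, name, allow_single = FALSE) {
  min_len <- if (allow_single) 1L else 2L
  if (length(x) < min_len || any(!is.finite(x)) || any(diff(x) <= 0))
    abort(sprintf("`%s` must be a finite, strictly increasing vector.", name))
  invisible(x)
}

# as.numeric that treats the literal "NA" quietly
num_or_na <- function(x) suppressWarnings(as.numeric(x))

# Round-half-to-even (base R round), the documented rounding rule for
# noiseless photon counts.
round_counts <- function(x) as.integer(round(x))
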