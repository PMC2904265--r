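# internal helpers

# Run `expr` under a local RNG state seeded with `seed`; if seed is NULL the
# global stream is used (and advanced) as-is.
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Fan a single seed out into n reproducible sub-seeds (kept < 2^31).
fan_seeds <- function(seed, n) {
  with_seed_or_stream(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite", name))
  }
  invisible(x)
}

# strict 3-point local maxima indices of a numeric vector (interior only)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] > x[i + 1]]
}
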