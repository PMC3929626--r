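# Internal helpers shared across modules.

# Evaluate `code` with a locally seeded RNG, restoring the caller's RNG state.
# All package randomness flows through this so that a single integer seed
# determines every generated object, without touching global state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed. Keeps results
# for different pipeline stages statistically independent while remaining
# a pure function of (seed, stream). Stays inside 32-bit integer range.
child_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * as.numeric(stream)) %% 2147483629) + 1L
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

assert_range <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a non-empty numeric range c(lo, hi).", name))
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

DNA_LETTERS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample() that treats `x` as a vector even when it has length 1.
resample <- function(x, n = 1, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}
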