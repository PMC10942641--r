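# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All exported stochastic functions funnel
# their randomness through this so that a single integer seed makes a whole
# analysis reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible sub-stream seed (e.g. one per recipient) from a
# master seed. Kept strictly below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, index) {
  (as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_fraction <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo && x <= hi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
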