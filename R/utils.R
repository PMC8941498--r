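# Internal helpers shared across modules.

# Run `code` under set.seed(seed) without disturbing the caller's RNG
# stream; generators are pure functions of (parameters, seed).
with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed from a root seed and integer coordinates
# (replicate index, arm, ...).  Simple LCG-style hash kept below 2^31 so
# the result is a valid R integer seed; all arithmetic stays < 2^53.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 69069 + as.double(k) * 1234567 + 362437) %% 2147483647
  }
  as.integer(h)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
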