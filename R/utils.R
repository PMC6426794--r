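# Internal helpers shared across modules.

# Clip a numeric vector to [lo, hi].
clip <- function(x, lo = 0, hi = 100) {
  pmin(pmax(x, lo), hi)
}

# Derive a reproducible child seed from a parent seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 7919) %% 2147483647)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (the previous .Random.seed is restored on exit).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
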