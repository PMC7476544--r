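# Internal helpers shared across modules.

# Log-spaced sequence (constant ratio between consecutive levels).
lseq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. Keeps multi-start draws deterministic without disturbing an
# enclosing simulation stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Replicate-level percent mobile from quantal counts.
percent_mobile <- function(n_exposed, n_immobile) {
  100 * (1 - n_immobile / n_exposed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_raytox <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "raytox_error")))
}
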