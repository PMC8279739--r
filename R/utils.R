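# Internal helpers: local RNG scoping and seed-stream derivation.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive `n` independent sub-stream seeds from one seed, so
# that the components of a session plan (pair order, formats, outcome order,
# sides, reward probabilities) can be regenerated independently.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# A random seed drawn from the current RNG, used when the caller passed NULL.
draw_seed <- function() sample.int(2147483646L, 1L)

`%||%` <- function(x, y) if (is.null(x)) y else x
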