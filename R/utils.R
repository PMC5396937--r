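# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random number stream. A `NULL` seed evaluates the
#' expression under the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for replicate `r` of a run seeded with `seed`.
# Kept strictly below 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, r) {
  as.integer((as.double(seed) + 104729 * as.double(r)) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample() without its size-1 surprise: sample1(5L) never means sample(1:5).
sample_exact <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
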