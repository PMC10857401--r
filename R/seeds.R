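#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library code never clobbers the caller's stream.
#'
#' @param seed Single non-negative integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("invalid argument: 'seed' must be a single non-negative integer")
  }
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
  expr
}

#' Derive reproducible sub-seeds from a master seed
#'
#' A master seed deterministically spawns independent sub-seeds for the
#' projection basis, ID vectors, data generation, and noise injection, so any
#' experiment is replayable component-wise. Sub-seeds stay below 2^31 - 1.
#'
#' @param seed Master seed.
#' @param n Number of sub-seeds to draw.
#' @return Integer vector of length `n`.
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}
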