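#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper: the global RNG state is saved, the given seed installed, and
#' the previous state restored on exit, so simulations are reproducible and
#' never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent sub-seeds from a master seed
#'
#' Generator-splitting scheme: the master seed seeds a temporary stream from
#' which `n` sub-seeds are drawn uniformly in `[1, 2^31 - 2]`. Composite
#' simulators hand one sub-seed to each internal component so that each
#' component's stream is reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' split_seeds(1, 3)
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
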