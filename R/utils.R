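#' Derive independent sub-seeds from a single master seed
#'
#' Monte-Carlo stages of the pipeline each need their own RNG stream while the
#' whole analysis stays a pure function of one user-supplied seed. Sub-seeds
#' are drawn as a block of integers from the master-seeded stream.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds required.
#' @return integer vector of length `n`, each usable with [set.seed()].
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run expr with a local RNG state seeded by `seed` (NULL = use current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Draw `n` indices from a discrete distribution given cumulative weights
# (cumw[length(cumw)] == 1). O(n log G), avoids sample.int's per-call
# weight-table rebuild in hot simulation loops.
sample_cumw <- function(cumw, n) {
  findInterval(stats::runif(n), cumw) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
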