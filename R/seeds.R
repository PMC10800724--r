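#' Deterministic seed derivation
#'
#' Derives a child seed from a root seed and a sequence of integer keys
#' (e.g. stage, subject, trial) by repeated modular mixing in a 31-bit
#' field, so that every stage/subject/trial of the pipeline draws from its
#' own reproducible substream. The result is always in `[1, 2^31 - 2]` and
#' is safe to pass to [set.seed()].
#'
#' @param seed root seed (non-negative integer).
#' @param ... integer keys identifying the substream.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.double(seed) %% m
  for (k in c(...)) {
    # multiplicative mixing; 48271 is the MINSTD multiplier
    x <- (x * 48271 + as.double(k) * 8191 + 1) %% m
  }
  as.integer(x %% (m - 1)) + 1L
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so probe draws never perturb an enclosing simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
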