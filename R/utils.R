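#' @keywords internal
"_PACKAGE"

# Missing-attribute sentinel used throughout the cohort store. An explicit
# string (not "" or NA in files) so that TSV round-trips are unambiguous.
MISSING_CODE <- "__missing__"

#' Derive independent sub-seeds from one master seed
#'
#' A single seed drives several conceptually independent random streams
#' (batch effects, noise, labels, artifacts, ...). Sub-seeds are drawn once
#' from the master seed so that consumers can re-seed per purpose and a change
#' in how one stream is consumed does not perturb the others.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run code under a local RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state, so
#' package internals never clobber a user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# column-wise population (N-denominator) variance
colvar_pop <- function(X) {
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

# column-wise sample (n-1) variance, n >= 2 required by callers
colvar_sample <- function(X) {
  n <- nrow(X)
  sw <- sweep(X, 2L, colMeans(X))
  colSums(sw^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
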