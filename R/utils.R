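## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generators do not
#' disturb the global random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

## scalar checks used by validity methods and constructors
.isCount <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < .Machine$double.eps^0.5
}

.isProb <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

.isPositive <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## coordinate column names for a given dimensionality
.axisNames <- function(dims) c("x_um", "y_um", "z_um")[seq_len(dims)]
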