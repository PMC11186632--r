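## Nearest-neighbor clustering statistic with confidence-based subsampling.
## The statistic follows the intravital-imaging convention: for each query
## cell of a subset, the mean Euclidean distance to its k nearest cells of
## the TOTAL population (both subsets combined), self excluded.

.resolveQuery <- function(pattern, query) {
  if (is.character(query) && length(query) == 1L &&
      query %in% unique(pattern@subset)) {
    which(pattern@subset == query)
  } else if (is.numeric(query)) {
    q <- as.integer(query)
    if (any(q < 1L) || any(q > nPoints(pattern)))
      .stopf("query indices out of range")
    q
  } else {
    .stopf("query must be a subset label or a vector of point indices")
  }
}

#' Mean distance to the k nearest reference cells
#'
#' For each query cell, the arithmetic mean of Euclidean distances to its
#' `k` nearest cells in the reference pattern, excluding the query cell
#' itself. Following the imaging convention the distance is computed on the
#' X/Y coordinates by default (`dims = 2`), even for 3D patterns; set
#' `dims = 3` to use the depth axis. Ties at the k-th neighbor are broken by
#' lowest point index.
#'
#' @param pattern a [PointPattern-class]: the reference population.
#' @param query a subset label (e.g. `"llpc"`) naming the query cells within
#'   `pattern`, or integer indices into it.
#' @param k number of neighbors (default 20).
#' @param dims 2 (drop depth axis) or 3.
#' @return numeric vector of per-query-cell mean distances (μm), named by
#'   point index.
#' @examples
#' pp <- genPointPattern(SpatialSimConfig(seed = 5))
#' head(knnMeanDistance(pp, "llpc", k = 20))
#' @export
knnMeanDistance <- function(pattern, query, k = 20, dims = 2) {
  stopifnot(is(pattern, "PointPattern"))
  if (!.isCount(k, min = 1L)) .stopf("k must be a positive integer")
  qi <- .resolveQuery(pattern, query)
  d <- min(as.integer(dims), ncol(pattern@coords))
  R <- pattern@coords[, seq_len(d), drop = FALSE]
  n <- nrow(R)
  if (n - 1L < k)
    .stopf("knnMeanDistance: only %d eligible reference points for k = %d",
           n - 1L, k)
  out <- numeric(length(qi))
  for (j in seq_along(qi)) {
    q <- R[qi[j], ]
    d2 <- rowSums((R - matrix(q, n, d, byrow = TRUE))^2)
    d2[qi[j]] <- Inf             # self-exclusion
    kd <- sort(d2, partial = k)[seq_len(k)]
    out[j] <- mean(sqrt(kd))
  }
  names(out) <- qi
  out
}

#' Survey sample size under confidence and margin of error
#'
#' Cochran's formula with maximal variance (p = 0.5) and finite-population
#' correction: `n0 = z^2 * 0.25 / margin^2` with `z` the two-sided normal
#' quantile for the confidence level, then `n = n0 / (1 + (n0 - 1) / N)`,
#' rounded up and capped at the population size.
#'
#' @param population population size (>= 1).
#' @param confidence confidence level in (0, 1), default 0.95.
#' @param margin margin of error in (0, 1), default 0.05.
#' @return integer sample size.
#' @examples
#' requiredSampleSize(1000)  # 278
#' requiredSampleSize(100)   # 80
#' @export
requiredSampleSize <- function(population, confidence = 0.95, margin = 0.05) {
  if (!.isCount(population, min = 1L)) .stopf("population must be >= 1")
  if (!(is.numeric(margin) && length(margin) == 1L && margin > 0 && margin < 1))
    .stopf("margin must be in (0, 1)")
  if (!(is.numeric(confidence) && length(confidence) == 1L &&
        confidence > 0 && confidence < 1))
    .stopf("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * 0.25 / margin^2
  n <- n0 / (1 + (n0 - 1) / population)
  min(as.integer(ceiling(n)), as.integer(population))
}

#' Subsampled nearest-neighbor statistic
#'
#' Draws a confidence-based random sample of query cells (without
#' replacement), computes [knnMeanDistance()] for each, and repeats for
#' `nIterations` independent draws (two in the original design). Values are
#' reported per iteration and pooled (concatenated).
#'
#' @param pattern a [PointPattern-class] reference population.
#' @param query subset label or indices of the query cells.
#' @param k neighbors (default 20).
#' @param nIterations independent random draws (default 2).
#' @param seed integer RNG seed (required).
#' @param confidence,margin sample-size parameters (defaults 0.95 / 0.05).
#' @param dims 2 or 3 (see [knnMeanDistance()]).
#' @return list with `perCell` (data.frame: `cell_index`, `iteration`,
#'   `mean_nn_um`), `pooledMean`, `iterationMeans`, `sampleSize`, and
#'   `populationSize`.
#' @examples
#' pp <- genPointPattern(SpatialSimConfig(seed = 5))
#' res <- subsampledNN(pp, "llpc", seed = 11)
#' res$pooledMean
#' @export
subsampledNN <- function(pattern, query, k = 20, nIterations = 2, seed,
                         confidence = 0.95, margin = 0.05, dims = 2) {
  qi <- .resolveQuery(pattern, query)
  pop <- length(qi)
  if (!pop) .stopf("subsampledNN: no query cells")
  nSamp <- requiredSampleSize(pop, confidence, margin)
  perCell <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(nIterations), function(it) {
      sel <- if (nSamp >= pop) qi else sort(sample(qi, nSamp))
      data.frame(cell_index = sel, iteration = it,
                 mean_nn_um = unname(knnMeanDistance(pattern, sel, k = k,
                                                     dims = dims)))
    }))
  })
  list(perCell = perCell,
       pooledMean = mean(perCell$mean_nn_um),
       iterationMeans = tapply(perCell$mean_nn_um, perCell$iteration, mean),
       sampleSize = nSamp, populationSize = pop)
}
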