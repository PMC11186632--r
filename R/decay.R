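## One-phase exponential decay fitting of labeled-cohort counts and
## bootstrap comparison of half-lives.

.KEPS <- 1e-10  # below this rate (per day) the half-life is reported infinite

#' Fit a one-phase decay model to cohort counts
#'
#' Nonlinear least squares on
#' `count(t) = (n0 - plateau) * exp(-k * t) + plateau`
#' fitted to raw counts (all replicates pooled), initialized from a
#' log-linear regression on the positive counts. The half-life is
#' `ln(2) / k`, reported as `Inf` when `k` is at machine scale. With four
#' timepoints a free plateau is weakly identified, so the plateau is fixed at
#' zero by default.
#'
#' @param series a [DecaySeries-class]; needs at least 3 distinct timepoints
#'   (4 for a free plateau) and at least one positive count.
#' @param plateau_mode `"zero"` (plateau fixed at 0, default) or `"free"`.
#' @return A [DecayFit-class]; non-convergence is flagged, never silently
#'   replaced.
#' @examples
#' ds <- genDecayCohort(DecaySimConfig(noiseCv = 0, nReplicates = 1, seed = 1))
#' halfLife(fitOnePhaseDecay(ds))
#' @export
fitOnePhaseDecay <- function(series, plateau_mode = c("zero", "free")) {
  stopifnot(is(series, "DecaySeries"))
  plateau_mode <- match.arg(plateau_mode)
  d <- series@data
  nt <- length(unique(d$day))
  need <- if (plateau_mode == "zero") 3L else 4L
  if (nt < need)
    .stopf("fitOnePhaseDecay: %d distinct timepoints required, got %d",
           need, nt)
  if (all(d$count <= 0)) .stopf("fitOnePhaseDecay: all counts are zero")

  ## constant counts: the no-decay limit is exact, with infinite half-life
  if (diff(range(d$count)) == 0)
    return(new("DecayFit", n0 = d$count[1L], k = 0, plateau = 0,
               tHalf = Inf, rss = 0, converged = TRUE,
               plateauMode = plateau_mode, nObs = nrow(d)))

  ## log-linear initialization on positive counts
  pos <- d$count > 0
  ll <- stats::lm(log(count) ~ day, data = d[pos, , drop = FALSE])
  k0 <- max(-unname(stats::coef(ll)[2L]), 0)
  n00 <- exp(unname(stats::coef(ll)[1L]))

  fit <- NULL
  converged <- FALSE
  if (plateau_mode == "zero") {
    fit <- tryCatch(
      minpack.lm::nlsLM(count ~ n0 * exp(-k * day), data = d,
                        start = list(n0 = n00, k = max(k0, 1e-6)),
                        lower = c(n0 = 0, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    plateau <- 0
  } else {
    p0 <- min(d$count) / 2
    fit <- tryCatch(
      minpack.lm::nlsLM(count ~ (n0 - plateau) * exp(-k * day) + plateau,
                        data = d,
                        start = list(n0 = n00, k = max(k0, 1e-6), plateau = p0),
                        lower = c(n0 = 0, k = 0, plateau = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(new("DecayFit", n0 = n00, k = k0, plateau = 0,
               tHalf = if (k0 > .KEPS) log(2) / k0 else Inf,
               rss = NA_real_, converged = FALSE,
               plateauMode = plateau_mode, nObs = nrow(d)))
  }
  cf <- stats::coef(fit)
  k <- unname(cf[["k"]])
  plateau <- if (plateau_mode == "free") unname(cf[["plateau"]]) else 0
  new("DecayFit", n0 = unname(cf[["n0"]]), k = k, plateau = plateau,
      tHalf = if (k > .KEPS) log(2) / k else Inf,
      rss = sum(stats::resid(fit)^2), converged = TRUE,
      plateauMode = plateau_mode, nObs = nrow(d))
}

.resampleSeries <- function(series) {
  d <- series@data
  parts <- lapply(split(d, d$day), function(dd) {
    dd[sample.int(nrow(dd), replace = TRUE), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  new("DecaySeries", data = out)
}

#' Compare two half-lives by case-resampling bootstrap
#'
#' Resamples replicate counts within each timepoint (independently for the
#' two series), refits both decay models, and reports the difference in
#' half-lives `a - b` with a percentile confidence interval.
#'
#' @param fit_a,fit_b converged [DecayFit-class] objects for the two groups.
#' @param series_a,series_b the corresponding [DecaySeries-class] data; every
#'   timepoint needs at least 2 replicates.
#' @param n_boot bootstrap iterations (default 500).
#' @param seed integer RNG seed (required).
#' @param conf CI level (default 0.95).
#' @return list with `delta` (point estimate `halfLife(a) - halfLife(b)`),
#'   `ci` (percentile interval), `boot` (bootstrap deltas; non-finite
#'   iterations dropped), and `n_boot_used`.
#' @export
compareHalfLives <- function(fit_a, fit_b, series_a, series_b, n_boot = 500,
                             seed, conf = 0.95) {
  stopifnot(is(fit_a, "DecayFit"), is(fit_b, "DecayFit"))
  if (!fit_a@converged || !fit_b@converged)
    .stopf("compareHalfLives: both fits must have converged")
  for (s in list(series_a, series_b)) {
    nrep <- vapply(split(s@data$replicate_id, s@data$day),
                   function(r) length(r), integer(1))
    if (any(nrep < 2L))
      .stopf("compareHalfLives: every timepoint needs >= 2 replicates")
  }
  mode <- fit_a@plateauMode
  boot <- withSeed(seed, vapply(seq_len(n_boot), function(i) {
    fa <- tryCatch(fitOnePhaseDecay(.resampleSeries(series_a), mode),
                   error = function(e) NULL)
    fb <- tryCatch(fitOnePhaseDecay(.resampleSeries(series_b), mode),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(fb) || !fa@converged || !fb@converged)
      return(NA_real_)
    fa@tHalf - fb@tHalf
  }, numeric(1)))
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  list(delta = fit_a@tHalf - fit_b@tHalf,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       boot = boot, n_boot_used = length(boot))
}
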