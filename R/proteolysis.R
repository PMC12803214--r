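#' Fit a proteolysis timecourse to a single exponential decay
#'
#' Least-squares fit of `F(t) = A exp(-k t)` to the fraction-intact
#' timecourse, with the amplitude free within `[0.8, 1.2]` (gel
#' densitometry baselines drift; no plateau term). Rate recovery is exact
#' on noiseless data. A timecourse that rises with time, or otherwise
#' defeats the decay model, is returned flagged (`converged = FALSE`)
#' rather than raising, since not every protein's decay is fittable.
#'
#' @param tc a [ProteolysisTimecourse-class] with >= 3 points
#' @return the timecourse with its `fit` slot set: `rate` (1/h),
#'   `amplitude`, `rateSe`, `converged`
#' @export
fitExponentialDecay <- function(tc) {
  stopifnot(methods::is(tc, "ProteolysisTimecourse"))
  pts <- timecoursePoints(tc)
  pts <- pts[!is.na(pts$fraction), , drop = FALSE]
  if (nrow(pts) < 3L)
    stopUsage("exponential fit needs >= 3 timepoints")
  t <- pts$time; f <- pts$fraction
  # log-linear slope as starting value; a rising course gives slope > 0
  pos <- f > 0
  slope <- if (sum(pos) >= 2L)
    unname(stats::coef(stats::lm(log(f[pos]) ~ t[pos]))[2L]) else -1
  rising <- slope > 0
  if (max(f) - min(f) < 1e-12) {
    # constant course: k = 0 exactly, amplitude at the (bounded) mean
    tc@fit <- list(rate = 0, amplitude = min(max(mean(f), 0.8), 1.2),
                   rateSe = 0, converged = TRUE)
    return(tc)
  }
  k_init <- max(-slope, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * exp(-k * t),
                      data = data.frame(t = t, f = f),
                      start = list(A = 1, k = k_init),
                      lower = c(0.8, 0), upper = c(1.2, Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tc@fit <- list(rate = NA_real_, amplitude = NA_real_,
                   rateSe = NA_real_, converged = FALSE)
    return(tc)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  tc@fit <- list(rate = unname(est["k"]), amplitude = unname(est["A"]),
                 rateSe = unname(se),
                 converged = !rising)
  tc
}

#' Trapezoidal area under a proteolysis timecourse
#'
#' Trapezoidal integral of fraction intact over time in hours — the simple
#' protease-sensitivity metric used when exponential fits are not
#' attainable. Missing fractions are dropped pairwise, never interpolated.
#'
#' @param tc a [ProteolysisTimecourse-class] with >= 2 points
#' @return area in fraction x hours; also stored in the returned object's
#'   `auc` slot when assigned back
#' @export
timecourseAUC <- function(tc) {
  stopifnot(methods::is(tc, "ProteolysisTimecourse"))
  pts <- timecoursePoints(tc)
  pts <- pts[!is.na(pts$fraction), , drop = FALSE]
  if (nrow(pts) < 2L)
    stopUsage("AUC needs >= 2 timepoints")
  pracma::trapz(pts$time, pts$fraction)
}

#' Single-timepoint proteolytic protection
#'
#' Difference in intact fraction between the stabilized and vehicle
#' samples at one optimized timepoint, `stabilized - vehicle`. Positive
#' values mean protection.
#'
#' @param vehicle,stabilized intact fractions in `[0, 1]`
#' @return protection delta (vectorised)
#' @examples protectionSingleTimepoint(0.2, 0.8)
#' @export
protectionSingleTimepoint <- function(vehicle, stabilized) {
  stopifnot(all(vehicle >= 0 & vehicle <= 1, na.rm = TRUE),
            all(stabilized >= 0 & stabilized <= 1, na.rm = TRUE))
  stabilized - vehicle
}

#' Pearson correlation of two stability metrics
#'
#' Sample Pearson correlation with a two-sided p value from the t
#' transform, as used to compare per-protein proteolysis and HDX stability
#' summaries. Pairs with a missing entry are deleted pairwise; zero
#' variance in either remaining vector is an error (the correlation is
#' undefined).
#'
#' @param x,y equal-length numeric vectors (>= 3 complete pairs)
#' @return list with `r` and `p`
#' @examples pearsonCorrelation(1:5, c(2, 4, 5, 4, 5))
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stopUsage("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopUsage("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopUsage("undefined correlation: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pair proteolysis and HDX stability metrics across proteins
#'
#' Joins two per-protein scalar metrics (for example proteolysis
#' timecourse AUC and HDX exchange AUC, or their stabilizer-induced
#' changes) and computes their Pearson correlation.
#'
#' @param x,y named numeric vectors (names are protein labels) or
#'   equal-length vectors with `proteins` given
#' @param proteins protein labels when `x`, `y` are unnamed
#' @param xlab,ylab metric labels
#' @return a [StabilityComparison-class]
#' @export
stabilityComparison <- function(x, y, proteins = NULL,
                                xlab = "proteolysis", ylab = "hdx") {
  if (is.null(proteins)) {
    if (is.null(names(x)) || is.null(names(y)))
      stopUsage("either name the metric vectors or give 'proteins'")
    proteins <- intersect(names(x), names(y))
    x <- x[proteins]; y <- y[proteins]
  }
  if (length(x) != length(y) || length(x) != length(proteins))
    stopUsage("metric vectors and protein labels must align")
  pc <- pearsonCorrelation(x, y)
  methods::new("StabilityComparison",
               metrics = data.frame(protein = proteins, x = unname(x),
                                    y = unname(y)),
               xlab = xlab, ylab = ylab, r = pc$r, p = pc$p)
}
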