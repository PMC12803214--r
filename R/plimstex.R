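#' Evaluate the unimolar protection model
#'
#' Predicted centroid uptake at total ligand concentration `L` under the
#' unimolar (one ligand per light-chain dimer) protection model.
#' `"hyperbolic"` (default): `D(L) = D0 + deltaDmax L / (ec50 + L)` — the
#' midpoint is the concentration of half-maximal effect, deliberately not
#' interpreted as a dissociation constant. `"quadratic_depletion"` replaces
#' `L` by the free-ligand concentration from the exact 1:1 dimer:ligand
#' mass balance at total dimer concentration `proteinTotal`, for users who
#' want a thermodynamic reading at concentrations comparable to the
#' protein's.
#'
#' @param d0 uptake at zero ligand, Da
#' @param deltaDmax asymptotic uptake change, Da (signed; protection is
#'   negative)
#' @param ec50 midpoint, uM (> 0)
#' @param L total ligand concentrations, uM
#' @param model `"hyperbolic"` or `"quadratic_depletion"`
#' @param proteinTotal total dimer concentration, uM
#' @return predicted uptake, Da (vectorised over `L`)
#' @examples
#' bindingModelEval(3.73, -1.37, 0.65, c(0, 0.65, 1e6))
#' @export
bindingModelEval <- function(d0, deltaDmax, ec50, L,
                             model = c("hyperbolic", "quadratic_depletion"),
                             proteinTotal = 0.25) {
  model <- match.arg(model)
  stopifnot(ec50 > 0, all(L >= 0))
  if (model == "hyperbolic") {
    d0 + deltaDmax * L / (ec50 + L)
  } else {
    s <- proteinTotal + L + ec50
    complex <- (s - sqrt(s^2 - 4 * proteinTotal * L)) / 2
    Lfree <- L - complex
    d0 + deltaDmax * Lfree / (ec50 + Lfree)
  }
}

#' Fit a PLIMSTEX titration to the unimolar protection model
#'
#' Nonlinear least squares of replicate-averaged centroid uptake against
#' ligand concentration. Initialisation is parameter-free: `D0` from the
#' uptake at the lowest concentration, `deltaDmax` from the uptake change
#' across the grid, `ec50` from the concentration nearest the
#' half-change. Degenerate flat series converge with `deltaDmax` near 0 and
#' are flagged unidentifiable rather than raising.
#'
#' Alongside the asymptotic amplitude, the fit reports `deltaAtMax`, the
#' fitted uptake change between the highest tested concentration and zero
#' ligand — the convention in which titration endpoints are quoted
#' (measured between the centroids of the m/z distributions at the top of
#' the titration and at zero ligand).
#'
#' @param series a [TitrationSeries-class] with >= 4 distinct
#'   concentrations
#' @param model `"hyperbolic"` (default) or `"quadratic_depletion"`
#' @param proteinTotal total dimer concentration for the depletion-aware
#'   model, uM
#' @param flatTolerance uptake span (Da) below which a series is treated as
#'   flat/unidentifiable
#' @return a [BindingFit-class]
#' @seealso [bindingModelEval()], [hyperbolicTitration()]
#' @export
fitTitration <- function(series,
                         model = c("hyperbolic", "quadratic_depletion"),
                         proteinTotal = 0.25, flatTolerance = 1e-8) {
  model <- match.arg(model)
  stopifnot(methods::is(series, "TitrationSeries"))
  pts <- titrationPoints(series)
  agg <- aggregateReplicates(pts, by = "conc", valueColumn = "uptake")
  agg <- agg[order(agg$conc), ]
  L <- agg$conc; y <- agg$mean
  if (length(unique(L)) < 4L)
    stopUsage("titration fitting needs >= 4 distinct concentrations")
  span <- max(y) - min(y)
  d0_init <- y[which.min(L)]
  dmax_init <- y[which.max(L)] - d0_init
  if (abs(dmax_init) <= flatTolerance) {
    # flat series: midpoint undetermined by construction
    return(methods::new("BindingFit", d0 = mean(y), deltaDmax = 0,
                        ec50 = NA_real_,
                        se = c(d0 = stats::sd(y) / sqrt(length(y)),
                               deltaDmax = NA_real_, ec50 = NA_real_),
                        residual = sum((y - mean(y))^2), model = model,
                        deltaAtMax = 0, maxConc = max(L),
                        unidentifiable = TRUE, converged = TRUE))
  }
  half <- d0_init + dmax_init / 2
  ec50_init <- L[L > 0][which.min(abs(y[L > 0] - half))]
  if (!length(ec50_init) || ec50_init <= 0) ec50_init <- stats::median(L[L > 0])
  df <- data.frame(L = L, y = y)
  # with >= 3 replicates everywhere, weight by the replicate variances
  w <- if (all(agg$n >= 3L) && all(is.finite(agg$sd)) && all(agg$sd > 0))
    agg$n / agg$sd^2 else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bindingModelEval(d0, dmax, ec50, L, model = model,
                           proteinTotal = proteinTotal),
      data = df, weights = w,
      start = list(d0 = d0_init, dmax = dmax_init, ec50 = ec50_init),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("titration fit failed to converge: ", conditionMessage(fit),
         " [n = ", length(L), ", span = ", signif(span, 3), " Da]",
         call. = FALSE)
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("d0", "deltaDmax", "ec50")
  predTop <- bindingModelEval(est["d0"], est["dmax"], est["ec50"], max(L),
                              model = model, proteinTotal = proteinTotal)
  unident <- abs(est["dmax"]) < 10 * max(flatTolerance, 1e-8) ||
    (!is.na(se["ec50"]) && is.finite(se["ec50"]) &&
       se["ec50"] > 100 * est["ec50"])
  methods::new("BindingFit",
               d0 = unname(est["d0"]), deltaDmax = unname(est["dmax"]),
               ec50 = unname(est["ec50"]), se = se,
               residual = sum(stats::resid(fit)^2), model = model,
               deltaAtMax = unname(predTop - est["d0"]), maxConc = max(L),
               unidentifiable = unname(unident), converged = TRUE)
}

#' Predicted titration curve of a fitted binding model
#'
#' @param fit a [BindingFit-class]
#' @param L ligand concentrations, uM
#' @param proteinTotal total dimer concentration for the depletion-aware
#'   model
#' @return data.frame with columns `conc`, `uptake`
#' @export
predictTitration <- function(fit, L, proteinTotal = 0.25) {
  stopifnot(methods::is(fit, "BindingFit"))
  data.frame(conc = L,
             uptake = bindingModelEval(fit@d0, fit@deltaDmax, fit@ec50, L,
                                       model = fit@model,
                                       proteinTotal = proteinTotal))
}

#' Centroid and bimodality of per-point titration spectra
#'
#' For each titration point's isotopic envelope, computes the centroid
#' uptake via [centroidMass()] and a bimodality score: the profile is split
#' at every peak boundary into two contiguous components, each represented
#' by its intensity-weighted mean, and the score is the largest fractional
#' reduction of intensity-weighted squared dispersion relative to the
#' unimodal (single-mean) description — near 0 for a unimodal envelope,
#' approaching 1 for two well-separated populations. The score is reported,
#' never thresholded.
#'
#' @param spectra list of peak data.frames (`mz`, `intensity`), one per
#'   titration point
#' @param charge charge state of the envelopes
#' @param m0 undeuterated neutral mass subtracted to express centroids as
#'   uptake (0 keeps absolute neutral mass)
#' @return data.frame with columns `centroid` (Da of uptake when `m0` is
#'   given) and `bimodality`
#' @export
mixtureCentroid <- function(spectra, charge = 1L, m0 = 0) {
  if (!length(spectra)) stopUsage("empty spectra list")
  one <- function(peaks) {
    peaks <- as.data.frame(peaks)
    names(peaks)[1:2] <- c("mz", "intensity")
    if (!nrow(peaks) || sum(peaks$intensity) <= 0)
      stopUsage("empty spectrum")
    cen <- centroidMass(peaks, charge) - m0
    w <- peaks$intensity / sum(peaks$intensity)
    mu <- sum(w * peaks$mz)
    ss1 <- sum(w * (peaks$mz - mu)^2)
    score <- 0
    if (nrow(peaks) > 1L && ss1 > 0) {
      for (cut in seq_len(nrow(peaks) - 1L)) {
        i1 <- seq_len(cut); i2 <- (cut + 1L):nrow(peaks)
        w1 <- sum(w[i1]); w2 <- sum(w[i2])
        if (w1 <= 0 || w2 <= 0) next
        mu1 <- sum(w[i1] * peaks$mz[i1]) / w1
        mu2 <- sum(w[i2] * peaks$mz[i2]) / w2
        ss2 <- sum(w[i1] * (peaks$mz[i1] - mu1)^2) +
          sum(w[i2] * (peaks$mz[i2] - mu2)^2)
        score <- max(score, 1 - ss2 / ss1)
      }
    }
    c(centroid = cen, bimodality = score)
  }
  out <- t(vapply(spectra, one, c(centroid = 0, bimodality = 0)))
  as.data.frame(out)
}
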