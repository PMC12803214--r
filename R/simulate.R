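#' Construct a synthetic HDX system
#'
#' Validating constructor for [SyntheticSystem-class]. When
#' `intrinsicRates` is omitted they are computed from the sequence with
#' [computeIntrinsicRates()]; passing `rateOverride` gives every exchanging
#' residue a uniform rate, which keeps simulated ground truth independent
#' of the coefficient table.
#'
#' Defaults are the study conditions: label fraction 0.9 (10-fold dilution
#' into D2O buffer), centroid noise SD 0.20 Da, H/D mass increment
#' 1.00628 Da. Back-exchange retention defaults to 0.85, a typical value
#' for a refrigerated LC-MS setup.
#'
#' @param protein a [ProteinEntry-class]
#' @param logProtection per-residue ln P (recycled if scalar)
#' @param intrinsicRates optional per-residue k_int (1/s)
#' @param rateOverride optional uniform intrinsic rate (1/s)
#' @param labelFraction maximal exchangeable fraction f_D
#' @param backExchangeRetention deuterium retention r in (0, 1]
#' @param noiseSd centroid noise SD, Da
#' @param deuteronMass mass increment per deuteron, Da
#' @param seed integer seed for all realisations drawn from this system
#' @param pD,temperature passed to [computeIntrinsicRates()] when rates are
#'   computed from the sequence
#' @return a validated [SyntheticSystem-class]
#' @examples
#' p <- ProteinEntry("toy", "QSVLTQAAGKLE")
#' syntheticSystem(p, logProtection = 3, rateOverride = 1)
#' @export
syntheticSystem <- function(protein, logProtection,
                            intrinsicRates = NULL, rateOverride = NULL,
                            labelFraction = 0.9,
                            backExchangeRetention = 0.85,
                            noiseSd = 0.20, deuteronMass = DEUTERON_MASS,
                            seed = 1L, pD = 7.4, temperature = 293.15) {
  n <- nchar(protein@sequence)
  if (length(logProtection) == 1L) logProtection <- rep(logProtection, n)
  if (any(logProtection < 0, na.rm = TRUE))
    stopUsage("negative protection (ln P must be >= 0)")
  if (is.null(intrinsicRates))
    intrinsicRates <- computeIntrinsicRates(protein@sequence, pD = pD,
                                            temperature = temperature,
                                            override = rateOverride)
  obj <- methods::new("SyntheticSystem", protein = protein,
                      logProtection = as.numeric(logProtection),
                      intrinsicRates = as.numeric(intrinsicRates),
                      labelFraction = labelFraction,
                      backExchangeRetention = backExchangeRetention,
                      noiseSd = noiseSd, deuteronMass = deuteronMass,
                      seed = as.integer(seed))
  methods::validObject(obj)
  obj
}

#' Construct a ligand-coupling specification
#'
#' @param midpoint protection midpoint concentration, uM
#' @param deltaLogProtection per-residue ln P increment in the bound state
#'   (length of the protein; zero outside the binding site). A named list
#'   `list(site = positions, delta = value)` expands to a sparse vector of
#'   length `n`.
#' @param mode `"fast_exchange"` (single envelope, rate mixing) or
#'   `"slow_two_population"` (bimodal envelopes)
#' @param n protein length, required for the sparse form
#' @return a validated [LigandCoupling-class]
#' @examples
#' ligandCoupling(0.65, list(site = 8:10, delta = 2), n = 12)
#' @export
ligandCoupling <- function(midpoint, deltaLogProtection,
                           mode = c("fast_exchange", "slow_two_population"),
                           n = NULL) {
  mode <- match.arg(mode)
  if (is.list(deltaLogProtection)) {
    if (is.null(n)) stopUsage("n is required with the sparse site form")
    d <- numeric(n)
    d[deltaLogProtection$site] <- deltaLogProtection$delta
    deltaLogProtection <- d
  }
  obj <- methods::new("LigandCoupling", midpoint = midpoint,
                      deltaLogProtection = as.numeric(deltaLogProtection),
                      mode = mode, stoichiometry = 1)
  methods::validObject(obj)
  obj
}

#' Construct a proteolysis decay model
#'
#' @param rate vehicle decay constant, 1/h
#' @param rateBound decay constant under saturating stabilizer, 1/h
#' @param noiseSd SD of fraction-intact noise
#' @param timepoints sampling times, hours (default: the 24 h window
#'   sampled from 1 min on a log-like grid)
#' @return a validated [ProteolysisModel-class]
#' @export
proteolysisModel <- function(rate, rateBound = rate, noiseSd = 0.05,
                             timepoints = c(1/60, 0.25, 1, 2, 5, 8, 24)) {
  obj <- methods::new("ProteolysisModel", rate = rate, rateBound = rateBound,
                      noiseSd = noiseSd, timepoints = sort(timepoints))
  methods::validObject(obj)
  obj
}

#' Fractional ligand occupancy
#'
#' Occupancy of the dimer binding site at total ligand concentration `L`.
#' The default `"hyperbolic"` form is the phenomenological
#' `theta = L / (midpoint + L)`; `"quadratic_depletion"` solves the exact
#' 1:1 dimer:ligand mass balance at total dimer concentration
#' `proteinTotal`, treating `midpoint` as a dissociation constant.
#'
#' @param L total ligand concentrations, uM
#' @param midpoint midpoint (or Kd for the quadratic form), uM
#' @param model occupancy model
#' @param proteinTotal total dimer concentration, uM (the titration
#'   experiment's 0.25 uM by default)
#' @return occupancies in `[0, 1]`
#' @export
thetaOccupancy <- function(L, midpoint,
                           model = c("hyperbolic", "quadratic_depletion"),
                           proteinTotal = 0.25) {
  model <- match.arg(model)
  stopifnot(all(L >= 0), midpoint > 0)
  if (model == "hyperbolic") return(L / (midpoint + L))
  s <- proteinTotal + L + midpoint
  complex <- (s - sqrt(s^2 - 4 * proteinTotal * L)) / 2
  complex / proteinTotal
}

# Per-residue EX2 uptake curves at one effective protection vector.
.ex2Curves <- function(kint, logP, fD, times) {
  kobs <- outer(kint * exp(-logP), times)  # n x length(times): k_eff * t
  D <- fD * (1 - exp(-kobs))
  D[kint == 0, ] <- 0
  dimnames(D) <- list(NULL, as.character(times))
  D
}

#' Simulate per-residue EX2 exchange
#'
#' Noiseless, deterministic per-residue deuterium fractions
#' `D_i(t) = f_D (1 - exp(-(k_int,i / P_i) t))` under the system's
#' protection factors, optionally perturbed by ligand binding at occupancy
#' `thetaBound`. In `fast_exchange` mode the free and bound observed rates
#' mix (`k_eff = (1 - theta) k_free + theta k_bound`) and a single matrix is
#' returned; in `slow_two_population` mode the two population curves are
#' returned separately with their weights.
#'
#' @param system a [SyntheticSystem-class]
#' @param times labeling times, seconds
#' @param thetaBound bound fraction in `[0, 1]`
#' @param coupling a [LigandCoupling-class], or `NULL` for apo simulation
#' @return `fast_exchange` (or no coupling): matrix residues x times.
#'   `slow_two_population`: list with elements `free`, `bound` (matrices)
#'   and `weights = c(1 - theta, theta)`.
#' @export
simulateResidueExchange <- function(system, times, thetaBound = 0,
                                    coupling = NULL) {
  stopifnot(all(times >= 0), thetaBound >= 0, thetaBound <= 1)
  kint <- system@intrinsicRates
  logP <- system@logProtection
  fD <- system@labelFraction
  if (is.null(coupling))
    return(.ex2Curves(kint, logP, fD, times))
  logPb <- logP + coupling@deltaLogProtection
  if (coupling@mode == "fast_exchange") {
    kEff <- (1 - thetaBound) * kint * exp(-logP) +
      thetaBound * kint * exp(-logPb)
    D <- fD * (1 - exp(-outer(kEff, times)))
    D[kint == 0, ] <- 0
    dimnames(D) <- list(NULL, as.character(times))
    D
  } else {
    list(free = .ex2Curves(kint, logP, fD, times),
         bound = .ex2Curves(kint, logPb, fD, times),
         weights = c(1 - thetaBound, thetaBound))
  }
}

# Retention for peptide index i: scalar recycled, or per-peptide vector.
.retentionFor <- function(system, i, npep) {
  r <- system@backExchangeRetention
  if (length(r) == 1L) r else r[(i - 1L) %% length(r) + 1L]
}

#' Simulate peptide-level HDX observations
#'
#' Realises the observables of a peptide-level HDX-MS experiment for a set
#' of peptides over a set of labeling times: the undeuterated centroid
#' `m0` (the peptide's monoisotopic mass), the observed centroid
#' `mt = m0 + r x true uptake + noise`, and the maximally deuterated control
#' `mmaxD = m0 + r x f_D x N_exch x deuteronMass` (noiseless by default,
#' same retention as the labeled samples). True uptake sums `D_i(t) x
#' deuteronMass` over the peptide's exchangeable reporters — every residue
#' except the peptide's first two (fast back exchange) and prolines.
#'
#' Realisations are reproducible under the system seed: the same system
#' simulated twice yields identical tables.
#'
#' @param system a [SyntheticSystem-class]
#' @param peptides data.frame (or 2-column matrix) of sequential `start`,
#'   `end` intervals, 1-based inclusive
#' @param times labeling times, seconds
#' @param thetaBound bound fraction in `[0, 1]`
#' @param coupling optional [LigandCoupling-class]
#' @param condition condition label stored on the records
#' @param replicates replicate observations per peptide x time
#' @param noiseSd centroid noise SD, Da; defaults to the system's
#' @param maxdNoise when TRUE the maxD controls also receive centroid noise
#' @return a [StateTable-class]
#' @export
simulatePeptideUptake <- function(system, peptides, times,
                                  thetaBound = 0, coupling = NULL,
                                  condition = "vehicle", replicates = 1L,
                                  noiseSd = system@noiseSd,
                                  maxdNoise = FALSE) {
  peptides <- as.data.frame(peptides)
  names(peptides)[1:2] <- c("start", "end")
  seqstr <- system@protein@sequence
  n <- nchar(seqstr)
  if (any(peptides$start < 1 | peptides$end > n))
    stopUsage("peptide interval outside the protein sequence")
  if (any(peptides$end - peptides$start + 1L < 3L))
    stopUsage("peptides must span at least 3 residues to carry a reporter")
  D <- simulateResidueExchange(system, times, thetaBound, coupling)
  slow <- is.list(D)
  fD <- system@labelFraction
  dm <- system@deuteronMass
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    s <- peptides$start[i]; e <- peptides$end[i]
    pep <- substr(seqstr, s, e)
    rep_idx <- peptideReporters(s, e, system@intrinsicRates)
    nexch <- length(rep_idx)
    if (nexch == 0L)
      stopUsage("peptide ", s, "-", e, " has no exchangeable reporters")
    trueU <- if (slow) {
      D$weights[1] * colSums(D$free[rep_idx, , drop = FALSE]) * dm +
        D$weights[2] * colSums(D$bound[rep_idx, , drop = FALSE]) * dm
    } else colSums(D[rep_idx, , drop = FALSE]) * dm
    r <- .retentionFor(system, i, nrow(peptides))
    m0 <- peptideMass(pep)
    g <- expand.grid(time = seq_along(times), replicate = seq_len(replicates))
    rows[[i]] <- data.frame(
      protein = system@protein@name, start = as.integer(s),
      end = as.integer(e), sequence = pep,
      condition = condition, exposure = times[g$time],
      m0 = m0, mt = m0 + r * trueU[g$time],
      mmaxD = m0 + r * fD * nexch * dm,
      replicate = as.integer(g$replicate), stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  if (noiseSd > 0 || maxdNoise) {
    rec <- withSeed(system@seed, {
      rec$mt <- rec$mt + stats::rnorm(nrow(rec), 0, noiseSd)
      if (maxdNoise)
        rec$mmaxD <- rec$mmaxD + stats::rnorm(nrow(rec), 0, noiseSd)
      rec
    })
  }
  tab <- StateTable(records = rec, proteins = list(system@protein))
  methods::validObject(tab)
  tab
}

#' Simulate an isotopic envelope of a partially deuterated peptide
#'
#' Deuteration-only envelope: the intensity at `j` incorporated deuterons is
#' the Poisson-binomial probability of `j` successes over the per-site
#' deuteration probabilities, and peaks are spaced by
#' `deuteronMass / charge` above `baseMz`. For a slow-interconversion
#' two-population system, pass a list of probability vectors with
#' `weights`; the envelope is then the weighted sum of the per-population
#' envelopes (bimodal when the populations are well separated).
#'
#' @param nSites number of exchangeable sites
#' @param siteProbabilities numeric vector of length `nSites` in `[0, 1]`,
#'   or a list of such vectors for a population mixture
#' @param baseMz m/z of the undeuterated centroid peak
#' @param charge positive integer charge state
#' @param deuteronMass mass increment per deuteron, Da
#' @param weights population weights (summing to 1) for the list form
#' @return data.frame with columns `mz`, `intensity` (intensities sum to 1)
#' @export
simulateIsotopeEnvelope <- function(nSites, siteProbabilities, baseMz,
                                    charge, deuteronMass = DEUTERON_MASS,
                                    weights = NULL) {
  if (charge <= 0 || charge != round(charge))
    stopUsage("charge must be a positive integer")
  pois_binom <- function(p) {
    if (length(p) != nSites)
      stopUsage("need one probability per site")
    if (any(p < 0 | p > 1)) stopUsage("site probabilities must be in [0, 1]")
    dist <- 1
    for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
    dist
  }
  if (is.list(siteProbabilities)) {
    if (is.null(weights) || length(weights) != length(siteProbabilities))
      stopUsage("population mixture needs one weight per component")
    dist <- Reduce(`+`, Map(function(p, w) w * pois_binom(p),
                            siteProbabilities, weights))
  } else dist <- pois_binom(siteProbabilities)
  data.frame(mz = baseMz + (0:nSites) * deuteronMass / charge,
             intensity = dist)
}

#' Simulate a PLIMSTEX titration from a mechanistic system
#'
#' Titrates ligand over a synthetic system: at each total ligand
#' concentration the occupancy `theta(L)` follows [thetaOccupancy()] (the
#' phenomenological hyperbola by default), peptide uptake is simulated at
#' the fixed labeling time, and the centroid uptake `mt - m0` of each
#' replicate is recorded. Deterministic under the system seed.
#'
#' @param system a [SyntheticSystem-class]
#' @param coupling a [LigandCoupling-class]
#' @param peptide sequential `c(start, end)` interval of the reporter
#'   peptide
#' @param ligandConcentrations total ligand concentrations, uM
#' @param exposure labeling time, seconds (default 5400 s = 90 min)
#' @param replicates replicates per concentration (experimental default 2)
#' @param occupancyModel passed to [thetaOccupancy()]
#' @param proteinTotal total dimer concentration for the depletion-aware
#'   occupancy, uM
#' @param noiseSd centroid noise SD, Da
#' @param withSpectra attach simulated isotopic envelopes (charge 1) per
#'   titration point
#' @return a [TitrationSeries-class]
#' @export
simulateTitration <- function(system, coupling, peptide,
                              ligandConcentrations, exposure = 5400,
                              replicates = 2L,
                              occupancyModel = "hyperbolic",
                              proteinTotal = 0.25,
                              noiseSd = system@noiseSd,
                              withSpectra = FALSE) {
  if (!length(ligandConcentrations))
    stopUsage("empty ligand concentration list")
  stopifnot(all(ligandConcentrations >= 0))
  s <- peptide[1]; e <- peptide[2]
  rep_idx <- peptideReporters(s, e, system@intrinsicRates)
  m0 <- peptideMass(substr(system@protein@sequence, s, e))
  r <- system@backExchangeRetention[1]
  dm <- system@deuteronMass
  theta <- thetaOccupancy(ligandConcentrations, coupling@midpoint,
                          occupancyModel, proteinTotal)
  pts <- list(); spectra <- list()
  for (ci in seq_along(ligandConcentrations)) {
    D <- simulateResidueExchange(system, exposure, theta[ci], coupling)
    if (is.list(D)) {
      uFree <- sum(D$free[rep_idx, 1]) * dm
      uBound <- sum(D$bound[rep_idx, 1]) * dm
      trueU <- D$weights[1] * uFree + D$weights[2] * uBound
      if (withSpectra)
        spec <- simulateIsotopeEnvelope(
          length(rep_idx),
          list(r * D$free[rep_idx, 1], r * D$bound[rep_idx, 1]),
          baseMz = m0 + .PROTON_MASS, charge = 1L, deuteronMass = dm,
          weights = D$weights)
    } else {
      trueU <- sum(D[rep_idx, 1]) * dm
      if (withSpectra)
        spec <- simulateIsotopeEnvelope(
          length(rep_idx), r * D[rep_idx, 1],
          baseMz = m0 + .PROTON_MASS, charge = 1L, deuteronMass = dm)
    }
    pts[[ci]] <- data.frame(conc = ligandConcentrations[ci],
                            replicate = seq_len(replicates),
                            uptake = r * trueU)
    if (withSpectra) spectra[[ci]] <- spec
  }
  pts <- do.call(rbind, pts)
  if (noiseSd > 0)
    pts$uptake <- withSeed(system@seed,
                           pts$uptake + stats::rnorm(nrow(pts), 0, noiseSd))
  alnMap <- if (nzchar(system@protein@alignmentRow))
    tryCatch(mapInterval(buildAlignmentMap(system@protein), s, e,
                         "sequential_to_alignment"),
             error = function(err) c(s, e)) else c(s, e)
  TitrationSeries(protein = system@protein@name,
                  peptide = as.integer(alnMap),
                  exposure = exposure, points = pts, spectra = spectra)
}

#' Generate a titration directly from protection-model parameters
#'
#' Phenomenological counterpart of [simulateTitration()]: generates
#' replicate centroid uptakes on a concentration grid directly from the
#' unimolar protection model `D(L) = D0 + deltaDmax theta(L)`,
#' `theta = L / (ec50 + L)`. With `deltaAt = "max"` (default) `deltaD` is
#' interpreted as the realized uptake change at the highest concentration
#' on the grid — the convention in which titration endpoints are quoted —
#' and the asymptotic amplitude is `deltaD / theta(max L)`; with
#' `"asymptote"` it is used as the amplitude directly.
#'
#' @param d0 uptake at zero ligand, Da
#' @param deltaD signed uptake change, Da (see `deltaAt`)
#' @param ec50 protection midpoint, uM
#' @param concentrations ligand concentrations, uM (default: the 2-fold
#'   serial-dilution grid 0.095-25 uM of the titration experiment,
#'   `25 / 2^(8:0)`)
#' @param exposure labeling time, seconds
#' @param replicates replicates per concentration
#' @param noiseSd centroid noise SD, Da (0 for a noiseless series)
#' @param seed seed for the noise draws
#' @param deltaAt `"max"` or `"asymptote"`
#' @param protein,peptide labels stored on the series
#' @return a [TitrationSeries-class]
#' @examples
#' ts <- hyperbolicTitration(3.73, -1.37, 0.65)
#' fitTitration(ts)
#' @export
hyperbolicTitration <- function(d0, deltaD, ec50,
                                concentrations = 25 / 2^(8:0),
                                exposure = 5400, replicates = 1L,
                                noiseSd = 0, seed = NULL,
                                deltaAt = c("max", "asymptote"),
                                protein = "synthetic",
                                peptide = c(NA_integer_, NA_integer_)) {
  deltaAt <- match.arg(deltaAt)
  if (!length(concentrations)) stopUsage("empty ligand concentration list")
  stopifnot(ec50 > 0, all(concentrations >= 0))
  dmax <- if (deltaAt == "max") {
    top <- max(concentrations)
    if (top <= 0) stopUsage("deltaAt = 'max' needs a positive concentration")
    deltaD / (top / (ec50 + top))
  } else deltaD
  g <- expand.grid(conc = concentrations, replicate = seq_len(replicates))
  g <- g[order(g$conc, g$replicate), ]
  uptake <- d0 + dmax * g$conc / (ec50 + g$conc)
  if (noiseSd > 0)
    uptake <- withSeed(seed, uptake + stats::rnorm(length(uptake), 0, noiseSd))
  TitrationSeries(protein = protein, peptide = as.integer(peptide),
                  exposure = exposure,
                  points = data.frame(conc = g$conc, replicate = g$replicate,
                                      uptake = uptake, row.names = NULL))
}

#' Simulate a limited-proteolysis timecourse
#'
#' Fraction intact `F(t) = exp(-k t)` plus Gaussian noise, clipped to
#' `[0, 1]`; the bound-state rate is used when `withLigand` is TRUE.
#'
#' @param model a [ProteolysisModel-class]
#' @param withLigand simulate the stabilizer-saturated condition
#' @param seed seed for the noise draws
#' @param protein protein label
#' @return a [ProteolysisTimecourse-class]
#' @export
simulateProteolysis <- function(model, withLigand = FALSE, seed = NULL,
                                protein = "synthetic") {
  k <- if (withLigand) model@rateBound else model@rate
  t <- model@timepoints
  f <- exp(-k * t)
  if (model@noiseSd > 0)
    f <- withSeed(seed, f + stats::rnorm(length(t), 0, model@noiseSd))
  f <- pmin(pmax(f, 0), 1)
  ProteolysisTimecourse(protein = protein,
                        condition = if (withLigand) "stabilizer" else "vehicle",
                        points = data.frame(time = t, fraction = f))
}
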