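AA_ONE_LETTER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' ProteinEntry: a protein with its row in the master alignment
#'
#' One protein of the study: its amino-acid sequence, its gapped row in the
#' shared master alignment, the alignment column separating the variable
#' (V_L) and constant (C_L) domains, and optional region annotations
#' (framework regions FR1-4, complementarity-determining regions CDR1-3) in
#' alignment coordinates.
#'
#' Sequential residue numbering is 1-based and intervals are inclusive on
#' both ends; alignment numbering is 1-based over the master alignment
#' columns. Removing the gap character `-` from `alignmentRow` must give back
#' `sequence` exactly.
#'
#' @slot name short protein identifier
#' @slot sequence amino-acid sequence, one-letter upper-case codes
#' @slot alignmentRow gapped sequence over the master alignment (`-` gaps);
#'   may be empty (`""`) when no alignment is attached
#' @slot domainBoundary alignment column separating the two structural
#'   domains (last column of the first domain), or `NA`
#' @slot regionAnnotations data.frame with columns `label`, `start`, `end`
#'   (alignment coordinates), possibly empty
#'
#' @examples
#' ProteinEntry("toy", "QSVLTQ")
#' @aliases ProteinEntry
#' @exportClass ProteinEntry
setClass("ProteinEntry",
  slots = c(
    name = "character",
    sequence = "character",
    alignmentRow = "character",
    domainBoundary = "numeric",
    regionAnnotations = "data.frame"
  ),
  prototype = list(
    name = NA_character_,
    sequence = "",
    alignmentRow = "",
    domainBoundary = NA_real_,
    regionAnnotations = data.frame(label = character(),
                                   start = integer(), end = integer())
  )
)

#' @param name,sequence,alignmentRow,domainBoundary,regionAnnotations see
#'   the slot descriptions
#' @rdname ProteinEntry-class
#' @export
ProteinEntry <- function(name, sequence, alignmentRow = "",
                         domainBoundary = NA_real_,
                         regionAnnotations = data.frame(
                           label = character(), start = integer(),
                           end = integer())) {
  obj <- methods::new("ProteinEntry", name = name,
                      sequence = toupper(sequence),
                      alignmentRow = toupper(alignmentRow),
                      domainBoundary = domainBoundary,
                      regionAnnotations = regionAnnotations)
  methods::validObject(obj)
  obj
}

setValidity("ProteinEntry", function(object) {
  msg <- character()
  seq <- object@sequence
  if (length(seq) != 1L || is.na(seq))
    return("'sequence' must be a single string")
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ONE_LETTER)
  if (length(bad))
    msg <- c(msg, sprintf("non-amino-acid characters in sequence: %s",
                          paste(unique(bad), collapse = ", ")))
  aln <- object@alignmentRow
  if (nzchar(aln)) {
    if (gsub("-", "", aln, fixed = TRUE) != seq)
      msg <- c(msg, "ungapped alignmentRow does not equal sequence")
    if (!is.na(object@domainBoundary) &&
        (object@domainBoundary < 1 || object@domainBoundary > nchar(aln)))
      msg <- c(msg, "domainBoundary outside alignment length")
  }
  ra <- object@regionAnnotations
  if (nrow(ra)) {
    if (!all(c("label", "start", "end") %in% names(ra)))
      msg <- c(msg, "regionAnnotations needs columns label, start, end")
    else {
      ord <- ra[order(ra$start), , drop = FALSE]
      if (nrow(ord) > 1L && any(ord$start[-1L] <= ord$end[-nrow(ord)]))
        msg <- c(msg, "regionAnnotations overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinEntry", function(object) {
  cat("ProteinEntry '", object@name, "': ", nchar(object@sequence),
      " residues", sep = "")
  if (nzchar(object@alignmentRow))
    cat(", aligned over ", nchar(object@alignmentRow), " columns", sep = "")
  cat("\n")
})

.state_cols <- c("protein", "start", "end", "sequence", "condition",
                 "exposure", "m0", "mt", "mmaxD", "replicate")

#' StateTable: peptide-level HDX observations
#'
#' Container for peptide-level HDX-MS centroid observations ("state data"):
#' one row per peptide x condition x exposure time x replicate, carrying the
#' undeuterated centroid `m0`, the observed centroid `mt` at the given
#' exposure, and the maximally deuterated control centroid `mmaxD` used for
#' back-exchange correction. Peptides whose centroid could not be determined
#' at a timepoint are kept as rows with `mt = NA` (flagged missing
#' downstream), never imputed.
#'
#' @slot records data.frame with columns `protein`, `start`, `end`,
#'   `sequence`, `condition`, `exposure` (seconds), `m0`, `mt`, `mmaxD`
#'   (Da; `NA` allowed for `mt` and `mmaxD`), `replicate`
#' @slot proteins list of [ProteinEntry-class] referenced by the records
#'   (possibly empty; when present, peptide sequences are validated against
#'   the protein sequence at their stated interval)
#'
#' @seealso [readPeptideStateTable()], [simulatePeptideUptake()],
#'   [uptakeTable()]
#' @export StateTable
#' @exportClass StateTable
StateTable <- setClass("StateTable",
  slots = c(records = "data.frame", proteins = "list"),
  prototype = list(
    records = stats::setNames(
      data.frame(character(), integer(), integer(), character(), character(),
                 numeric(), numeric(), numeric(), numeric(), integer()),
      c("protein", "start", "end", "sequence", "condition",
        "exposure", "m0", "mt", "mmaxD", "replicate")),
    proteins = list()
  )
)

setValidity("StateTable", function(object) {
  rec <- object@records
  if (!all(.state_cols %in% names(rec)))
    return(sprintf("records must have columns: %s",
                   paste(.state_cols, collapse = ", ")))
  msg <- character()
  if (nrow(rec)) {
    if (any(rec$exposure < 0, na.rm = TRUE))
      msg <- c(msg, "negative exposure times")
    if (any(rec$end < rec$start + 2L))
      msg <- c(msg, "peptides shorter than 3 residues (end < start + 2)")
    if (any(nchar(rec$sequence) != rec$end - rec$start + 1L))
      msg <- c(msg, "peptide sequence length disagrees with [start, end]")
    both <- !is.na(rec$m0) & !is.na(rec$mmaxD)
    if (any(both & rec$mmaxD <= rec$m0))
      msg <- c(msg, "mmaxD must exceed m0 (degenerate maxD control)")
  }
  prot <- object@proteins
  if (length(prot)) {
    if (!all(vapply(prot, is, logical(1), "ProteinEntry")))
      msg <- c(msg, "proteins must be ProteinEntry objects")
    else {
      seqs <- stats::setNames(
        vapply(prot, function(p) p@sequence, character(1)),
        vapply(prot, function(p) p@name, character(1)))
      known <- rec$protein %in% names(seqs)
      for (i in which(known)) {
        s <- seqs[[rec$protein[i]]]
        if (rec$end[i] > nchar(s) ||
            substr(s, rec$start[i], rec$end[i]) != rec$sequence[i]) {
          msg <- c(msg, sprintf(
            "row %d: peptide sequence disagrees with protein '%s' at %d-%d",
            i, rec$protein[i], rec$start[i], rec$end[i]))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("records", "StateTable", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("proteinEntries", "StateTable", function(object) object@proteins)

setMethod("show", "StateTable", function(object) {
  rec <- object@records
  cat("StateTable:", nrow(rec), "peptide observations\n")
  if (nrow(rec)) {
    cat("  proteins:  ", paste(unique(rec$protein), collapse = ", "), "\n")
    cat("  conditions:", paste(unique(rec$condition), collapse = ", "), "\n")
    cat("  exposures: ", paste(sort(unique(rec$exposure)), collapse = ", "),
        "s\n")
    cat("  missing centroids:", sum(is.na(rec$mt)), "\n")
  }
})

#' ResidueExchangeMap: per-residue percent deuteration
#'
#' Percent deuteration reduced to single-residue resolution on master
#' alignment coordinates, stored as a 3-d array position x condition x time
#' with a parallel coverage mask. Positions with no reporting peptide are
#' uncovered (`NA` deuteration, `FALSE` coverage).
#'
#' @slot protein protein name
#' @slot positions integer alignment positions (rows of the array)
#' @slot conditions condition labels
#' @slot times exposure times, seconds
#' @slot percentD numeric array `[position, condition, time]`, `NA` where
#'   uncovered
#' @slot coverage logical array of the same shape
#' @export ResidueExchangeMap
#' @exportClass ResidueExchangeMap
ResidueExchangeMap <- setClass("ResidueExchangeMap",
  slots = c(protein = "character", positions = "integer",
            conditions = "character", times = "numeric",
            percentD = "array", coverage = "array"))

setValidity("ResidueExchangeMap", function(object) {
  d <- c(length(object@positions), length(object@conditions),
         length(object@times))
  if (!identical(dim(object@percentD), d))
    return("percentD dimensions disagree with positions/conditions/times")
  if (!identical(dim(object@coverage), d))
    return("coverage dimensions disagree with percentD")
  if (any(!is.na(object@percentD) & !object@coverage))
    return("percentD present at uncovered cells")
  if (any(is.infinite(object@percentD)))
    return("non-finite percentD values")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("deuteration", "ResidueExchangeMap", function(object) object@percentD)

#' @rdname accessors
#' @export
setMethod("coverage", "ResidueExchangeMap", function(object) object@coverage)

setMethod("show", "ResidueExchangeMap", function(object) {
  cat("ResidueExchangeMap for '", object@protein, "': ",
      length(object@positions), " positions x ",
      length(object@conditions), " conditions x ",
      length(object@times), " times; ",
      round(100 * mean(object@coverage), 1), "% covered\n", sep = "")
})

#' DifferenceMap: condition-vs-condition residue deuteration difference
#'
#' Cellwise percent-deuteration difference `%D(A) - %D(B)` between two
#' conditions of a [ResidueExchangeMap-class], defined only where both
#' conditions are covered. Stabilizer-induced protection appears as negative
#' values.
#'
#' @slot protein protein name
#' @slot positions alignment positions
#' @slot times exposure times, seconds
#' @slot deltaPercentD numeric matrix `[position, time]`, `NA` where either
#'   condition is uncovered
#' @slot conditionPair character vector `c(A, B)`; the stored values are
#'   A minus B
#' @export DifferenceMap
#' @exportClass DifferenceMap
DifferenceMap <- setClass("DifferenceMap",
  slots = c(protein = "character", positions = "integer", times = "numeric",
            deltaPercentD = "matrix", conditionPair = "character"))

setValidity("DifferenceMap", function(object) {
  if (!identical(dim(object@deltaPercentD),
                 c(length(object@positions), length(object@times))))
    return("deltaPercentD dimensions disagree with positions/times")
  if (length(object@conditionPair) != 2L)
    return("conditionPair must be length 2")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("deuteration", "DifferenceMap", function(object) object@deltaPercentD)

setMethod("show", "DifferenceMap", function(object) {
  cat("DifferenceMap for '", object@protein, "': ",
      object@conditionPair[1], " - ", object@conditionPair[2], ", ",
      length(object@positions), " positions x ", length(object@times),
      " times\n", sep = "")
})

#' SyntheticSystem: ground truth for the forward simulator
#'
#' Defines a synthetic HDX experiment: a protein, its per-residue natural-log
#' protection factors and intrinsic exchange rates, the maximal exchangeable
#' deuterium fraction set by the labeling dilution, per-experiment
#' back-exchange retention, centroid noise, and the seed making every
#' realisation reproducible.
#'
#' Prolines and the protein's N-terminal residue are non-reporting
#' (`intrinsicRates = 0` there); the constructor enforces this.
#'
#' @slot protein a [ProteinEntry-class]
#' @slot logProtection per-residue ln P (>= 0 at exchanging residues)
#' @slot intrinsicRates per-residue intrinsic rate k_int, 1/s
#' @slot labelFraction maximal exchangeable fraction f_D in (0, 1]; default
#'   0.9, the 10-fold dilution into D2O labeling buffer
#' @slot backExchangeRetention per-peptide deuterium retention r in (0, 1]
#'   (scalar applied to all peptides, or named by peptide)
#' @slot noiseSd centroid noise SD in Da; default 0.20, the stated precision
#'   of peptide deuterium determination
#' @slot deuteronMass mass increment per deuteron, Da (H/D difference
#'   1.00628 by default)
#' @slot seed integer seed
#' @seealso [syntheticSystem()] for the validating constructor
#' @export
#' @exportClass SyntheticSystem
setClass("SyntheticSystem",
  slots = c(protein = "ProteinEntry", logProtection = "numeric",
            intrinsicRates = "numeric", labelFraction = "numeric",
            backExchangeRetention = "numeric", noiseSd = "numeric",
            deuteronMass = "numeric", seed = "integer"))

setValidity("SyntheticSystem", function(object) {
  n <- nchar(object@protein@sequence)
  msg <- character()
  if (length(object@logProtection) != n)
    msg <- c(msg, "logProtection length must equal protein length")
  if (length(object@intrinsicRates) != n)
    msg <- c(msg, "intrinsicRates length must equal protein length")
  else {
    res <- strsplit(object@protein@sequence, "")[[1]]
    nonrep <- which(res == "P" | seq_len(n) == 1L)
    if (any(object@intrinsicRates[nonrep] != 0))
      msg <- c(msg, "prolines and residue 1 must have intrinsic rate 0")
    if (any(object@intrinsicRates < 0))
      msg <- c(msg, "negative intrinsic rates")
  }
  if (any(object@logProtection < 0, na.rm = TRUE))
    msg <- c(msg, "negative log protection")
  if (object@labelFraction <= 0 || object@labelFraction > 1)
    msg <- c(msg, "labelFraction must be in (0, 1]")
  if (any(object@backExchangeRetention <= 0 |
          object@backExchangeRetention > 1))
    msg <- c(msg, "backExchangeRetention must be in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@deuteronMass <= 0) msg <- c(msg, "deuteronMass must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSystem", function(object) {
  cat("SyntheticSystem on '", object@protein@name, "' (",
      nchar(object@protein@sequence), " residues): f_D = ",
      object@labelFraction, ", retention = ",
      paste(unique(object@backExchangeRetention), collapse = "/"),
      ", noise SD = ", object@noiseSd, " Da, seed = ", object@seed,
      "\n", sep = "")
})

#' LigandCoupling: ligand-dependent protection of a synthetic system
#'
#' Couples ligand occupancy to per-residue protection: in the bound state
#' each residue's ln P is incremented by `deltaLogProtection` (zero outside
#' the binding site). The `fast_exchange` mode mixes free/bound exchange
#' rates (fast interconversion on the exchange timescale, single envelope);
#' `slow_two_population` keeps the two populations separate, producing
#' bimodal envelopes weighted (1 - theta, theta). Stoichiometry is one
#' ligand per light-chain dimer.
#'
#' @slot midpoint protection midpoint concentration, uM
#' @slot deltaLogProtection per-residue ln P increment in the bound state
#' @slot mode `"fast_exchange"` or `"slow_two_population"`
#' @slot stoichiometry ligands per dimer (1)
#' @seealso [ligandCoupling()]
#' @export
#' @exportClass LigandCoupling
setClass("LigandCoupling",
  slots = c(midpoint = "numeric", deltaLogProtection = "numeric",
            mode = "character", stoichiometry = "numeric"))

setValidity("LigandCoupling", function(object) {
  msg <- character()
  if (object@midpoint <= 0) msg <- c(msg, "midpoint must be > 0")
  if (any(object@deltaLogProtection < 0))
    msg <- c(msg, "deltaLogProtection must be >= 0")
  if (!object@mode %in% c("fast_exchange", "slow_two_population"))
    msg <- c(msg, "mode must be 'fast_exchange' or 'slow_two_population'")
  if (object@stoichiometry != 1)
    msg <- c(msg, "stoichiometry is fixed at one ligand per dimer")
  if (length(msg)) msg else TRUE
})

#' ProteolysisModel: generative model of limited-proteolysis decay
#'
#' First-order decay of the intact-protein fraction, with separate rate
#' constants for the vehicle and the stabilizer-saturated state, Gaussian
#' noise on the measured fractions, and the sampling timepoints in hours.
#'
#' @slot rate vehicle decay constant k_p, 1/h
#' @slot rateBound decay constant with saturating stabilizer, 1/h
#' @slot noiseSd SD of fraction-intact noise
#' @slot timepoints sampling times, hours
#' @seealso [proteolysisModel()], [simulateProteolysis()]
#' @export
#' @exportClass ProteolysisModel
setClass("ProteolysisModel",
  slots = c(rate = "numeric", rateBound = "numeric", noiseSd = "numeric",
            timepoints = "numeric"))

setValidity("ProteolysisModel", function(object) {
  msg <- character()
  if (object@rate < 0 || object@rateBound < 0)
    msg <- c(msg, "rates must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(object@timepoints < 0)) msg <- c(msg, "timepoints must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TitrationSeries: a PLIMSTEX ligand titration
#'
#' Deuterium uptake of one peptide at a fixed labeling time across a ligand
#' concentration series (2-fold serial dilutions in the source experiment),
#' with replicates, and optionally the raw isotopic envelopes behind each
#' point.
#'
#' @slot protein protein name
#' @slot peptide integer interval `c(start, end)` in alignment coordinates
#' @slot exposure labeling time, seconds (default experiment: 5400 s =
#'   90 min)
#' @slot points data.frame with columns `conc` (uM), `replicate`, `uptake`
#'   (Da)
#' @slot spectra optional list, per titration point, of peak matrices
#'   (columns `mz`, `intensity`)
#' @export TitrationSeries
#' @exportClass TitrationSeries
TitrationSeries <- setClass("TitrationSeries",
  slots = c(protein = "character", peptide = "integer", exposure = "numeric",
            points = "data.frame", spectra = "list"),
  prototype = list(protein = NA_character_, peptide = c(NA_integer_, NA_integer_),
                   exposure = 5400, spectra = list(),
                   points = data.frame(conc = numeric(), replicate = integer(),
                                       uptake = numeric())))

setValidity("TitrationSeries", function(object) {
  pts <- object@points
  if (!all(c("conc", "replicate", "uptake") %in% names(pts)))
    return("points needs columns conc, replicate, uptake")
  if (nrow(pts) && any(pts$conc < 0))
    return("negative ligand concentrations")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("titrationPoints", "TitrationSeries", function(object) object@points)

setMethod("show", "TitrationSeries", function(object) {
  cc <- sort(unique(object@points$conc))
  cat("TitrationSeries '", object@protein, "' peptide ",
      object@peptide[1], "-", object@peptide[2], ", ",
      object@exposure, " s exposure: ", length(cc),
      " concentrations", sep = "")
  if (length(cc))
    cat(" (", format(min(cc)), "-", format(max(cc)), " uM)", sep = "")
  cat(", ", nrow(object@points), " points\n", sep = "")
})

#' BindingFit: fitted unimolar protection model
#'
#' Result of fitting a PLIMSTEX titration to the unimolar (one ligand per
#' dimer) protection model: baseline uptake at zero ligand `d0`, signed
#' asymptotic uptake change `deltaDmax`, midpoint `ec50` (the concentration
#' of half-maximal protection; not a dissociation constant), asymptotic
#' standard errors, and the signed change at the highest tested
#' concentration (`deltaAtMax`, the quantity quoted as Delta-D).
#'
#' @slot d0 uptake at zero ligand, Da
#' @slot deltaDmax asymptotic uptake change at saturation, Da (signed)
#' @slot ec50 protection midpoint, uM
#' @slot se named numeric of asymptotic standard errors (d0, deltaDmax, ec50)
#' @slot residual residual sum of squares of the fit
#' @slot model `"hyperbolic"` or `"quadratic_depletion"`
#' @slot deltaAtMax fitted uptake at the highest tested concentration minus
#'   `d0`, Da (signed)
#' @slot maxConc highest tested ligand concentration, uM
#' @slot unidentifiable flag: TRUE when the data are flat and the midpoint
#'   is not determined
#' @slot converged fitter convergence flag
#' @seealso [fitTitration()]
#' @export
#' @exportClass BindingFit
setClass("BindingFit",
  slots = c(d0 = "numeric", deltaDmax = "numeric", ec50 = "numeric",
            se = "numeric", residual = "numeric", model = "character",
            deltaAtMax = "numeric", maxConc = "numeric",
            unidentifiable = "logical", converged = "logical"))

setValidity("BindingFit", function(object) {
  if (length(object@ec50) == 1L && !is.na(object@ec50) && object@ec50 <= 0)
    return("ec50 must be > 0")
  TRUE
})

#' @describeIn BindingFit fitted coefficients as a named vector
#'   (`d0`, `deltaDmax`, `ec50`)
#' @param object a `BindingFit`
#' @param ... ignored
#' @export
setMethod("coef", "BindingFit", function(object, ...)
  c(d0 = object@d0, deltaDmax = object@deltaDmax, ec50 = object@ec50))

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit (", object@model, " model)\n", sep = "")
  cat(sprintf("  D0        = %.4g Da (se %.3g)\n", object@d0, object@se["d0"]))
  cat(sprintf("  deltaDmax = %.4g Da (se %.3g)\n",
              object@deltaDmax, object@se["deltaDmax"]))
  cat(sprintf("  EC50      = %.4g uM (se %.3g)\n",
              object@ec50, object@se["ec50"]))
  cat(sprintf("  deltaD at %.4g uM = %.4g Da\n",
              object@maxConc, object@deltaAtMax))
  if (object@unidentifiable)
    cat("  NOTE: flat titration; midpoint unidentifiable\n")
})

#' ProteolysisTimecourse: fraction intact versus time
#'
#' A limited-proteolysis timecourse of one protein under one condition:
#' fraction of intact protein at each sampling time, with the exponential
#' decay fit and the trapezoidal area attached once computed.
#'
#' @slot protein protein name
#' @slot condition `"vehicle"` or `"stabilizer"`
#' @slot points data.frame with columns `time` (hours, strictly increasing)
#'   and `fraction` (intact fraction in `[0, 1]`)
#' @slot fit list with elements `rate` (1/h), `amplitude`, `rateSe`,
#'   `converged`, or empty before fitting
#' @slot auc trapezoidal area under the curve, fraction x hours, or `NA`
#' @export ProteolysisTimecourse
#' @exportClass ProteolysisTimecourse
ProteolysisTimecourse <- setClass("ProteolysisTimecourse",
  slots = c(protein = "character", condition = "character",
            points = "data.frame", fit = "list", auc = "numeric"),
  prototype = list(protein = NA_character_, condition = "vehicle",
                   points = data.frame(time = numeric(), fraction = numeric()),
                   fit = list(), auc = NA_real_))

setValidity("ProteolysisTimecourse", function(object) {
  pts <- object@points
  if (!all(c("time", "fraction") %in% names(pts)))
    return("points needs columns time, fraction")
  if (nrow(pts) > 1L && any(diff(pts$time) <= 0))
    return("times must be strictly increasing")
  if (nrow(pts) && any(pts$fraction < 0 | pts$fraction > 1, na.rm = TRUE))
    return("fractions must lie in [0, 1]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("timecoursePoints", "ProteolysisTimecourse",
          function(object) object@points)

setMethod("show", "ProteolysisTimecourse", function(object) {
  cat("ProteolysisTimecourse '", object@protein, "' (", object@condition,
      "): ", nrow(object@points), " timepoints", sep = "")
  if (length(object@fit))
    cat(sprintf(", k = %.3g 1/h%s", object@fit$rate,
                if (isTRUE(object@fit$converged)) "" else " (not converged)"))
  if (!is.na(object@auc)) cat(sprintf(", AUC = %.3g", object@auc))
  cat("\n")
})

#' StabilityComparison: proteolysis versus HDX stability metrics
#'
#' Per-protein pairing of two scalar stability summaries (for example
#' proteolysis timecourse AUC against HDX exchange-curve AUC) with their
#' Pearson correlation and two-sided p value.
#'
#' @slot metrics data.frame with columns `protein`, `x`, `y`
#' @slot xlab,ylab metric labels
#' @slot r Pearson correlation coefficient
#' @slot p two-sided p value from the t transform
#' @seealso [stabilityComparison()]
#' @export
#' @exportClass StabilityComparison
setClass("StabilityComparison",
  slots = c(metrics = "data.frame", xlab = "character", ylab = "character",
            r = "numeric", p = "numeric"))

setValidity("StabilityComparison", function(object) {
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    return("r outside [-1, 1]")
  TRUE
})

setMethod("show", "StabilityComparison", function(object) {
  cat("StabilityComparison: ", object@xlab, " vs ", object@ylab, " over ",
      nrow(object@metrics), " proteins; R = ", signif(object@r, 3),
      ", p = ", signif(object@p, 3), "\n", sep = "")
})
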