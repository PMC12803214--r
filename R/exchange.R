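#' Deuterium uptake from centroid masses
#'
#' Uptake is the centroid mass of the deuterated peptide minus that of its
#' undeuterated form, `mt - m0`. Vectorised; a missing centroid yields `NA`
#' (flagged missing downstream), not an error.
#'
#' @param m0 undeuterated centroid(s), Da
#' @param mt observed centroid(s), Da
#' @return uptake in Da
#' @examples computeUptake(1000.00, 1003.50)
#' @export
computeUptake <- function(m0, mt) mt - m0

#' Back-exchange-corrected percent deuteration
#'
#' The maxD normalisation: `%D = 100 (mt - m0) / (mmaxD - m0)`, where
#' `mmaxD` is the centroid of the maximally deuterated control of the same
#' peptide. Because numerator and denominator share the same per-peptide
#' deuterium retention, back exchange cancels exactly. Values slightly
#' outside `[0, 100]` arise from centroid noise on small denominators and
#' are preserved; beyond `[-tolerance, 100 + tolerance]` they are flagged
#' `out_of_range` (and excluded from residue reduction by default).
#'
#' @param m0,mt,mmaxD centroid masses, Da (vectorised)
#' @param tolerance out-of-range tolerance in %D units (default 5)
#' @return data.frame with columns `uptake` (Da), `percentD`, `flag`
#'   (`"ok"`, `"missing"`, `"out_of_range"`)
#' @examples
#' computePercentD(1000, 1002.5, 1005)  # 50 %
#' @export
computePercentD <- function(m0, mt, mmaxD, tolerance = 5) {
  n <- max(length(m0), length(mt), length(mmaxD))
  m0 <- rep_len(m0, n); mt <- rep_len(mt, n); mmaxD <- rep_len(mmaxD, n)
  degenerate <- !is.na(m0) & !is.na(mmaxD) & mmaxD <= m0
  if (any(degenerate))
    stopUsage("degenerate maxD control: mmaxD <= m0 for ",
              sum(degenerate), " record(s)")
  uptake <- computeUptake(m0, mt)
  percentD <- 100 * uptake / (mmaxD - m0)
  flag <- rep("ok", n)
  flag[!is.na(percentD) &
         (percentD < -tolerance | percentD > 100 + tolerance)] <- "out_of_range"
  flag[is.na(mt) | is.na(m0) | is.na(mmaxD)] <- "missing"
  percentD[is.na(mt) | is.na(m0) | is.na(mmaxD)] <- NA_real_
  data.frame(uptake = uptake, percentD = percentD, flag = flag)
}

#' Per-record uptake and percent deuteration of a state table
#'
#' Applies [computeUptake()] and [computePercentD()] to every record of a
#' [StateTable-class], returning the records annotated with `uptake`,
#' `percentD` and `flag` columns.
#'
#' @param table a [StateTable-class]
#' @param tolerance passed to [computePercentD()]
#' @return data.frame of records plus `uptake`, `percentD`, `flag`
#' @export
uptakeTable <- function(table, tolerance = 5) {
  stopifnot(methods::is(table, "StateTable"))
  rec <- records(table)
  cbind(rec, computePercentD(rec$m0, rec$mt, rec$mmaxD, tolerance))
}

#' Aggregate replicate uptake measurements
#'
#' Collapses replicates of each peptide x condition x exposure cell to the
#' arithmetic mean, reporting dispersion as the range (max minus min, 0 for
#' singletons) — the convention in which duplicate titrations are plotted —
#' plus the SD when three or more replicates are present.
#'
#' @param values numeric vector of replicate measurements (one cell), or a
#'   data.frame holding a `value` column plus grouping columns
#' @param by when `values` is a data.frame: character vector of grouping
#'   column names
#' @param valueColumn name of the measurement column in the data.frame form
#' @return for a vector: list with `mean`, `range`, `n`, `sd` (`NA` when
#'   n < 3). For a data.frame: one row per group with those statistics.
#' @examples
#' aggregateReplicates(c(3.6, 3.8))
#' @export
aggregateReplicates <- function(values,
                                by = c("protein", "start", "end",
                                       "condition", "exposure"),
                                valueColumn = "uptake") {
  if (is.data.frame(values)) {
    if (!valueColumn %in% names(values))
      stopUsage("no column '", valueColumn, "' to aggregate")
    by <- intersect(by, names(values))
    groups <- interaction(values[by], drop = TRUE, lex.order = TRUE)
    out <- do.call(rbind, lapply(split(values, groups), function(g) {
      s <- aggregateReplicates(g[[valueColumn]])
      cbind(g[1L, by, drop = FALSE],
            data.frame(mean = s$mean, range = s$range, n = s$n, sd = s$sd))
    }))
    rownames(out) <- NULL
    return(out)
  }
  values <- values[!is.na(values)]
  if (!length(values)) stopUsage("no replicate values to aggregate")
  list(mean = mean(values),
       range = if (length(values) > 1L) max(values) - min(values) else 0,
       n = length(values),
       sd = if (length(values) >= 3L) stats::sd(values) else NA_real_)
}

#' Neutral centroid mass of an isotopic envelope
#'
#' Intensity-weighted mean m/z of the peak list, converted to neutral mass:
#' `centroid = z * (mz_mean - proton mass)`.
#'
#' @param peaks data.frame (or 2-column matrix) with columns `mz`,
#'   `intensity`
#' @param charge positive integer charge state
#' @return neutral centroid mass, Da
#' @examples
#' centroidMass(data.frame(mz = c(500, 502), intensity = c(1, 1)), 1)
#' @export
centroidMass <- function(peaks, charge) {
  peaks <- as.data.frame(peaks)
  names(peaks)[1:2] <- c("mz", "intensity")
  if (charge <= 0 || charge != round(charge))
    stopUsage("charge must be a positive integer")
  if (!nrow(peaks) || sum(peaks$intensity) <= 0)
    stopUsage("envelope has no positive intensity")
  if (any(peaks$intensity < 0)) stopUsage("negative peak intensities")
  mz <- sum(peaks$mz * peaks$intensity) / sum(peaks$intensity)
  charge * (mz - .PROTON_MASS)
}
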