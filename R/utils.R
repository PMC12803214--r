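# Monoisotopic residue masses (Da) used to give simulated peptides a
# physically plausible undeuterated centroid.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.WATER_MASS <- 18.010565
.PROTON_MASS <- 1.007276

#' Default H/D mass increment per exchanged deuteron (Da)
#' @export
DEUTERON_MASS <- 1.00628

#' The labeling-time grid of the continuous-exchange experiment
#'
#' The six labeling times used throughout: 10 s, 1 min, 10 min, 1 h, 4 h and
#' 16 h, in seconds.
#'
#' @return numeric vector of six times in seconds
#' @examples hdxLabelingTimes()
#' @export
hdxLabelingTimes <- function() c(10, 60, 600, 3600, 14400, 57600)

#' Parse exposure-time tokens into seconds
#'
#' Accepts bare numbers (seconds) and tokens of the form `"10 s"`,
#' `"1 min"`, `"90 min"`, `"16 h"` (also `sec`/`m`/`hr`/`hour`), as exported
#' state tables vary in their time dialect.
#'
#' @param x character or numeric vector of exposures
#' @return numeric vector of exposures in seconds
#' @examples
#' parseExposure(c("10 s", "1 min", "16 h", "42"))
#' @export
parseExposure <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  bare <- grepl("^[0-9.eE+-]+$", x)
  out[bare] <- as.numeric(x[bare])
  m <- regmatches(x, regexec("^([0-9.]+)\\s*([A-Za-z]+)$", x))
  for (i in which(!bare)) {
    if (length(m[[i]]) == 3L) {
      val <- as.numeric(m[[i]][2])
      unit <- tolower(m[[i]][3])
      mult <- switch(unit,
                     s = , sec = , secs = , second = , seconds = 1,
                     m = , min = , mins = , minute = , minutes = 60,
                     h = , hr = , hrs = , hour = , hours = 3600,
                     NA_real_)
      out[i] <- val * mult
    }
  }
  if (anyNA(out))
    stop("unparseable exposure token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

# Monoisotopic neutral peptide mass; stops on unknown residue codes.
peptideMass <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  sum(.RESIDUE_MASS[res]) + .WATER_MASS
}

# Indices (within the whole protein) of residues that report exchange for a
# peptide [start, end]: the peptide's first two residues are excluded (fast
# back exchange at the N-terminus) as are residues with zero intrinsic rate
# (prolines, protein residue 1).
peptideReporters <- function(start, end, intrinsicRates) {
  idx <- (start + 2L):end
  idx[intrinsicRates[idx] > 0]
}

# Run `expr` under `seed` when non-NULL, leaving the caller's RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

stopUsage <- function(...) stop(..., call. = FALSE)
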