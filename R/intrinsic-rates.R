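# Reference exchange rates for an unstructured poly-DL-alanine backbone in
# D2O at 20 C (log10; acid/base in 1/(M min), water in 1/min), Arrhenius
# activation energies in kcal/mol, and the D2O autoionisation pK. The
# per-residue side-chain inductive factors ship as a versioned CSV resource
# (inst/extdata/intrinsic_rate_coefficients_v1.csv).
.RATE_REF <- list(
  log_kA = 1.62, log_kB = 10.05, log_kW = -1.5,
  Ea_A = 14, Ea_B = 17, Ea_W = 19,
  pKD = 15.05, Tref = 293.15, Rgas = 1.987e-3)

.rateCoefficients <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "intrinsic_rate_coefficients_v1.csv",
                          package = "hdxlc")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE,
                                row.names = "residue")
    }
    cache
  }
})

#' Intrinsic amide exchange rates of an unstructured chain
#'
#' Sequence-dependent intrinsic (chemical) backbone amide exchange rates
#' from the standard reference-rate method: acid-, base- and
#' water-catalysed terms referenced to poly-DL-alanine, modulated by the
#' side-chain inductive factors of each residue and its predecessor plus
#' terminal-group corrections, with Arrhenius temperature correction of
#' each catalytic term. Titratable side chains are treated in their
#' neutral-pD (deprotonated) forms, adequate for the pD 7-8.5 regime of
#' typical labeling buffers.
#'
#' Prolines (no amide hydrogen) and the protein's N-terminal residue (fast
#' back-exchanging alpha-amine neighbour) are non-reporting and get rate 0.
#'
#' With `override` given, every exchanging residue receives that uniform
#' rate instead; the non-reporting rules still apply. All simulation-facing
#' defaults in this package use the override so that downstream results do
#' not depend on the coefficient table.
#'
#' @param sequence amino-acid string, one-letter codes
#' @param pD pD of the labeling buffer (operational scale), in `[2, 10]`
#' @param temperature labeling temperature, K, in `[273, 333]`
#' @param override optional uniform rate (1/s) applied to all exchanging
#'   residues
#' @return numeric vector of per-residue rates, 1/s
#' @examples
#' computeIntrinsicRates("ASA", override = 1.0)  # c(0, 1, 1)
#' computeIntrinsicRates("QSVLTQPPS", pD = 7.4, temperature = 293.15)
#' @export
computeIntrinsicRates <- function(sequence, pD = 7.4, temperature = 293.15,
                                  override = NULL) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, AA_ONE_LETTER)
  if (length(bad))
    stopUsage("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n <- length(res)
  nonReporting <- res == "P" | seq_len(n) == 1L
  if (!is.null(override)) {
    stopifnot(is.numeric(override), override >= 0)
    k <- rep(override, n)
    k[nonReporting] <- 0
    return(k)
  }
  if (pD < 2 || pD > 10) stopUsage("pD must lie in [2, 10]")
  if (temperature < 273 || temperature > 333)
    stopUsage("temperature must lie in [273, 333] K")
  cf <- .rateCoefficients()
  r <- .RATE_REF
  arrh <- function(Ea)
    exp(-Ea / r$Rgas * (1 / temperature - 1 / r$Tref))
  k <- numeric(n)
  for (i in seq_len(n)[!nonReporting]) {
    aSelf <- cf[res[i], "acid_self"]
    bSelf <- cf[res[i], "base_self"]
    aPrev <- cf[res[i - 1L], "acid_prev"]
    bPrev <- cf[res[i - 1L], "base_prev"]
    if (i == 2L) {  # amide next to the free N-terminal amine
      aPrev <- aPrev + cf["NT", "acid_prev"]
      bPrev <- bPrev + cf["NT", "base_prev"]
    }
    if (i == n) {   # C-terminal carboxylate acts on the last amide
      aSelf <- aSelf + cf["CT", "acid_self"]
      bSelf <- bSelf + cf["CT", "base_self"]
    }
    kA <- 10^(r$log_kA + aSelf + aPrev - pD) * arrh(r$Ea_A)
    kB <- 10^(r$log_kB + bSelf + bPrev + pD - r$pKD) * arrh(r$Ea_B)
    kW <- 10^(r$log_kW + bSelf + bPrev) * arrh(r$Ea_W)
    k[i] <- (kA + kB + kW) / 60  # table is per minute; report per second
  }
  k
}
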