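# Shared fixtures and independent oracles for the suite.

# A proline-free toy protein long enough for several peptides.
toyEntry <- function(name = "toy",
                     sequence = "QSVLTQAAGKLEWNVFSTDKARGYHEQMILCN")
  ProteinEntry(name, sequence)

# Uniform-rate, uniform-protection system: closed forms are easy to state.
uniformSystem <- function(entry = toyEntry(), logP = 0, rate = 1,
                          fD = 0.9, r = 0.85, noiseSd = 0, seed = 1L,
                          deuteronMass = DEUTERON_MASS)
  syntheticSystem(entry, logProtection = logP, rateOverride = rate,
                  labelFraction = fD, backExchangeRetention = r,
                  noiseSd = noiseSd, deuteronMass = deuteronMass,
                  seed = seed)

# A random (but seeded) system for property loops; sequences avoid proline
# so reporter bookkeeping in hand computations stays simple.
randomSystem <- function(seed, n = 24, noiseSd = 0) {
  aa <- setdiff(c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","S","T","W","Y","V"), character(0))
  withr::with_seed(seed, {
    seqstr <- paste(sample(aa, n, replace = TRUE), collapse = "")
    syntheticSystem(ProteinEntry(paste0("rnd", seed), seqstr),
                    logProtection = stats::runif(n, 0, 5),
                    rateOverride = stats::runif(1, 0.001, 1),
                    labelFraction = stats::runif(1, 0.7, 1),
                    backExchangeRetention = stats::runif(1, 0.31, 1),
                    noiseSd = noiseSd, seed = seed)
  })
}

alignmentFixture <- function()
  system.file("extdata", "synthetic_lc_alignment.fasta", package = "hdxlc")

# Independent bounded-least-squares oracle: projected gradient descent on
# ||A x - b||^2 with box constraints. Deliberately different from the
# package's L-BFGS-B route.
oracleBoundedLS <- function(A, b, lo = 0, hi = 100) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  step <- 1 / (2 * max(eigen(AtA, symmetric = TRUE,
                             only.values = TRUE)$values))
  x <- rep((lo + hi) / 2, ncol(A))
  for (it in seq_len(2e5)) {
    g <- 2 * (AtA %*% x - Atb)
    xn <- pmin(pmax(x - step * g, lo), hi)
    if (max(abs(xn - x)) < 1e-13) { x <- xn; break }
    x <- xn
  }
  as.numeric(x)
}

# Build a StateTable directly from a per-residue %D pattern: peptide %D is
# the mean of its reporters' values, encoded into centroids with retention
# r so the maxD correction is exercised.
stateTableFromPattern <- function(pattern, peptides, r = 0.85,
                                  condition = "vehicle", exposure = 60,
                                  protein = "pat") {
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    s <- peptides$start[i]; e <- peptides$end[i]
    rep_idx <- setdiff((s + 2L):e, 1L)
    nex <- length(rep_idx)
    m0 <- 1000 + i
    mmaxD <- m0 + r * nex * DEUTERON_MASS
    mt <- m0 + r * mean(pattern[rep_idx]) / 100 * nex * DEUTERON_MASS
    data.frame(protein = protein, start = s, end = e,
               sequence = strrep("A", e - s + 1L),
               condition = condition, exposure = exposure,
               m0 = m0, mt = mt, mmaxD = mmaxD, replicate = 1L)
  })
  StateTable(records = do.call(rbind, rows))
}
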