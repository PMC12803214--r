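test_that("the shipped alignment maps peptide 101-110 to AL 98-107", {
  entries <- readAlignment(alignmentFixture())
  al <- entries[[which(vapply(entries, function(e) e@name, "") == "AL")]]
  m <- buildAlignmentMap(al)
  expect_identical(mapInterval(m, 101, 110, "alignment_to_sequential"),
                   c(98L, 107L))
  expect_identical(mapInterval(m, 98, 107, "sequential_to_alignment"),
                   c(101L, 110L))
  expect_identical(substr(al@sequence, 98, 107), "NWVFGGGTKL")
})

test_that("coordinate maps handle gaps, identity, and range errors", {
  id <- buildAlignmentMap(ProteinEntry("x", "QSVLT"))
  expect_identical(mapInterval(id, 2, 4, "sequential_to_alignment"), c(2L, 4L))
  gappy <- ProteinEntry("g", "QSVL", alignmentRow = "QS--VL")
  m <- buildAlignmentMap(gappy)
  expect_true(all(is.na(m$alnToSeq[3:4])))
  expect_identical(mapInterval(m, 3, 4, "alignment_to_sequential"), integer(0))
  expect_identical(mapInterval(m, 2, 3, "sequential_to_alignment"), c(2L, 5L))
  expect_error(mapInterval(m, 0, 2, "alignment_to_sequential"), "range")
  bad <- methods::new("ProteinEntry", name = "b", sequence = "QS",
                      alignmentRow = "")
  bad@alignmentRow <- "QT"
  expect_error(buildAlignmentMap(bad), "inconsistent")
})

test_that("a single consistent peptide spreads its %D over its reporters", {
  st <- stateTableFromPattern(rep(40, 12),
                              data.frame(start = 2, end = 9))
  map <- reduceToResidues(st)
  got <- deuteration(map)[, 1, 1]
  expect_equal(got[4:9], rep(40, 6), ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(is.na(got[1:3])))                 # never covered
  expect_true(all(!coverage(map)[1:3, , ]))
  expect_error(reduceToResidues(StateTable()), "no usable")
})

test_that("nnls reduction matches an independent bounded-LS oracle", {
  pattern <- c(0, 0, 0, 20, 80, 40, 60, 30, 70, 50, 10, 0)
  peptides <- data.frame(start = rep(2, 8), end = 4:11)  # nested: full rank
  st <- stateTableFromPattern(pattern, peptides)
  map <- reduceToResidues(st, method = "nnls")
  got <- deuteration(map)[4:11, 1, 1]
  # oracle: same design matrix, projected-gradient solver
  reps <- lapply(seq_len(nrow(peptides)),
                 function(i) (peptides$start[i] + 2L):peptides$end[i])
  residues <- sort(unique(unlist(reps)))
  A <- matrix(0, nrow(peptides), length(residues))
  for (i in seq_len(nrow(peptides))) A[i, match(reps[[i]], residues)] <- 1
  b <- vapply(seq_len(nrow(peptides)),
              function(i) mean(pattern[reps[[i]]]) * length(reps[[i]]),
              numeric(1))
  expect_equal(unname(got), oracleBoundedLS(A, b), tolerance = 1e-6)
  # and, the system being exactly determined, both equal the truth
  expect_equal(unname(got), pattern[4:11], tolerance = 1e-6)
})

test_that("weighted average and nnls agree on consistent overlapping input", {
  pattern <- rep(55, 14)
  peptides <- data.frame(start = c(2, 5, 8), end = c(9, 12, 13))
  st <- stateTableFromPattern(pattern, peptides)
  wa <- deuteration(reduceToResidues(st, "weighted_average"))[, 1, 1]
  nn <- deuteration(reduceToResidues(st, "nnls"))[, 1, 1]
  cov <- !is.na(wa)
  expect_equal(wa[cov], nn[cov], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(wa[cov], rep(55, sum(cov)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # consistency: averaging the map back over each peptide's reporters
  # reproduces the peptide %D
  for (i in seq_len(nrow(peptides))) {
    rep_idx <- (peptides$start[i] + 2L):peptides$end[i]
    expect_equal(mean(wa[rep_idx]), 55, tolerance = 1e-9)
  }
})

test_that("difference maps are antisymmetric and respect coverage", {
  pattern <- c(0, 0, 0, 20, 80, 40, 60, 30, 70, 50, 10, 0)
  stA <- stateTableFromPattern(pattern, data.frame(start = 2, end = 11),
                               condition = "stabilizer")
  stB <- stateTableFromPattern(pmin(pattern + 10, 100),
                               data.frame(start = c(2, 3), end = c(11, 12)),
                               condition = "vehicle")
  st <- StateTable(records = rbind(records(stA), records(stB)))
  map <- reduceToResidues(st)
  d1 <- differenceMap(map, "stabilizer", "vehicle")
  d2 <- differenceMap(map, "vehicle", "stabilizer")
  expect_equal(deuteration(d1), -deuteration(d2))
  # zero difference of a condition with itself
  same <- differenceMap(map, "vehicle", "vehicle")
  vals <- deuteration(same)
  expect_true(all(vals[!is.na(vals)] == 0))
  # residue 12's reporter cell exists only for vehicle: absent in the diff
  expect_true(is.na(deuteration(d1)[12, 1]))
  expect_error(differenceMap(map, "nope", "vehicle"), "unknown condition")
})

test_that("ligand protection shows as non-positive residue differences", {
  sys <- uniformSystem(logP = 2, rate = 1e-3)
  n <- nchar(sys@protein@sequence)
  cpl <- ligandCoupling(0.65, list(site = 8:14, delta = 2), n = n)
  peps <- data.frame(start = c(2, 6, 10), end = c(11, 15, 19))
  veh <- simulatePeptideUptake(sys, peps, hdxLabelingTimes(),
                               condition = "vehicle")
  bnd <- simulatePeptideUptake(sys, peps, hdxLabelingTimes(), thetaBound = 1,
                               coupling = cpl, condition = "stabilizer")
  st <- StateTable(records = rbind(records(veh), records(bnd)),
                   proteins = list(sys@protein))
  map <- reduceToResidues(st)
  d <- differenceMap(map, "stabilizer", "vehicle")
  vals <- deuteration(d)[8:14, ]
  expect_true(all(vals[!is.na(vals)] <= 1e-9))
})

test_that("exchange AUC integrates %D over log10 time", {
  arr <- array(50, c(2, 1, 6)); cov <- array(TRUE, dim(arr))
  map <- ResidueExchangeMap(protein = "p", positions = 1:2,
                            conditions = "vehicle",
                            times = hdxLabelingTimes(),
                            percentD = arr, coverage = cov)
  res <- exchangeAUC(map, "vehicle")
  width <- log10(57600) - log10(10)
  expect_equal(res$perResidue, c(`1` = 50 * width, `2` = 50 * width),
               tolerance = 1e-9)
  expect_equal(res$auc, 2 * 50 * width, tolerance = 1e-9)
  # linearity: halving %D halves the area; zero map gives zero
  half <- ResidueExchangeMap(protein = "p", positions = 1:2,
                             conditions = "vehicle",
                             times = hdxLabelingTimes(),
                             percentD = arr / 2, coverage = cov)
  expect_equal(exchangeAUC(half, "vehicle")$auc, res$auc / 2)
  zero <- ResidueExchangeMap(protein = "p", positions = 1:2,
                             conditions = "vehicle",
                             times = hdxLabelingTimes(),
                             percentD = arr * 0, coverage = cov)
  expect_equal(exchangeAUC(zero, "vehicle")$auc, 0)
  expect_error(exchangeAUC(ResidueExchangeMap(
    protein = "p", positions = 1:2, conditions = "vehicle", times = 10,
    percentD = array(1, c(2, 1, 1)), coverage = array(TRUE, c(2, 1, 1))),
    "vehicle"), "2 timepoints")
})

test_that("exchange AUC uses only residues covered in every condition", {
  arr <- array(NA_real_, c(3, 2, 2)); cov <- array(FALSE, dim(arr))
  arr[1:3, 1, ] <- 10; cov[1:3, 1, ] <- TRUE       # vehicle covers all
  arr[1:2, 2, ] <- 10; cov[1:2, 2, ] <- TRUE       # stabilizer misses res 3
  map <- ResidueExchangeMap(protein = "p", positions = 1:3,
                            conditions = c("vehicle", "stabilizer"),
                            times = c(10, 100), percentD = arr,
                            coverage = cov)
  res <- exchangeAUC(map, "vehicle")
  expect_identical(res$residues, 1:2)
  expect_equal(res$auc, 2 * 10 * 1, tolerance = 1e-9)
  # residue and time ordering of the input does not matter
  perm <- c(3, 1, 2)
  mp <- ResidueExchangeMap(protein = "p", positions = as.integer(perm),
                           conditions = c("vehicle", "stabilizer"),
                           times = c(10, 100),
                           percentD = arr[perm, , , drop = FALSE],
                           coverage = cov[perm, , , drop = FALSE])
  expect_equal(exchangeAUC(mp, "vehicle")$auc, res$auc)
})
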