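test_that("EX2 closed form, saturation, and infinite protection", {
  entry <- toyEntry()
  # k_int = 0.1/s, P = 10 => k_obs t = 1 at t = 100 s
  sys <- uniformSystem(entry, logP = log(10), rate = 0.1)
  D <- simulateResidueExchange(sys, c(100, 1e9))
  expect_equal(unname(D[3, 1]), 0.9 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(unname(D[3, 2]), 0.9, tolerance = 1e-9)  # t -> Inf: f_D
  expect_equal(D[1, ], c(0, 0), ignore_attr = TRUE)  # N-terminal silent

  frozen <- uniformSystem(entry, logP = Inf, rate = 0.1)
  expect_true(all(simulateResidueExchange(frozen, hdxLabelingTimes()) == 0))
  expect_error(syntheticSystem(entry, logProtection = -1, rateOverride = 1),
               "negative protection")
})

test_that("uptake is monotone in time, protection, and occupancy", {
  for (seed in 1:10) {
    sys <- randomSystem(seed)
    times <- sort(withr::with_seed(seed, stats::runif(5, 1, 1e5)))
    D <- simulateResidueExchange(sys, times)
    expect_true(all(apply(D, 1, function(x) all(diff(x) >= 0))))
    # increasing every ln P decreases uptake
    sys2 <- syntheticSystem(sys@protein, sys@logProtection + 0.5,
                            intrinsicRates = sys@intrinsicRates,
                            labelFraction = sys@labelFraction,
                            backExchangeRetention = sys@backExchangeRetention,
                            noiseSd = 0, seed = sys@seed)
    expect_true(all(simulateResidueExchange(sys2, times) <= D + 1e-15))
    # increasing theta under protective coupling decreases uptake
    cpl <- ligandCoupling(1, rep(1, nchar(sys@protein@sequence)))
    Dlo <- simulateResidueExchange(sys, times, 0.2, cpl)
    Dhi <- simulateResidueExchange(sys, times, 0.8, cpl)
    expect_true(all(Dhi <= Dlo + 1e-15))
  }
})

test_that("peptide observables match the hand-computed uptake chain", {
  # All reporters at D_i = 0.5: f_D (1 - e^{-kt}) = 0.5 at kt = ln(9/4)
  entry <- toyEntry()
  sys <- uniformSystem(entry, logP = 0, rate = 1, fD = 0.9, r = 0.85)
  t <- log(9 / 4)
  st <- simulatePeptideUptake(sys, data.frame(start = 2, end = 11), t)
  rec <- records(st)
  # 10-residue peptide, first two excluded: 8 reporters
  expect_equal(rec$mt - rec$m0, 8 * 0.5 * 0.85 * 1.00628, tolerance = 1e-9)
  expect_equal(rec$mmaxD - rec$m0, 8 * 0.9 * 0.85 * 1.00628, tolerance = 1e-12)

  st0 <- simulatePeptideUptake(sys, data.frame(start = 2, end = 11), 0)
  expect_equal(records(st0)$mt, records(st0)$m0)  # t = 0: no uptake

  expect_error(simulatePeptideUptake(sys, data.frame(start = 2, end = 3), t),
               "at least 3")
})

test_that("seeded simulation is bit-reproducible", {
  sys <- uniformSystem(noiseSd = 0.2, seed = 99L)
  peps <- data.frame(start = c(2, 5), end = c(11, 14))
  a <- simulatePeptideUptake(sys, peps, hdxLabelingTimes(), replicates = 2L)
  b <- simulatePeptideUptake(sys, peps, hdxLabelingTimes(), replicates = 2L)
  expect_identical(records(a), records(b))
  tc1 <- simulateProteolysis(proteolysisModel(0.3), seed = 4L)
  tc2 <- simulateProteolysis(proteolysisModel(0.3), seed = 4L)
  expect_identical(timecoursePoints(tc1), timecoursePoints(tc2))
})

test_that("isotope envelopes are Poisson-binomial with the right centroid", {
  flat <- simulateIsotopeEnvelope(5, rep(0, 5), 500, 1)
  expect_equal(flat$intensity, c(1, rep(0, 4 + 1)))
  expect_equal(flat$mz[1], 500)

  env <- simulateIsotopeEnvelope(10, rep(0.3, 10), 500, 1)
  shift <- centroidMass(env, 1) - centroidMass(data.frame(500, 1), 1)
  expect_equal(shift, 10 * 0.3 * DEUTERON_MASS, tolerance = 1e-9)

  mix <- simulateIsotopeEnvelope(10, list(rep(0.1, 10), rep(0.6, 10)),
                                 500, 1, weights = c(0.5, 0.5))
  c1 <- centroidMass(simulateIsotopeEnvelope(10, rep(0.1, 10), 500, 1), 1)
  c2 <- centroidMass(simulateIsotopeEnvelope(10, rep(0.6, 10), 500, 1), 1)
  expect_equal(centroidMass(mix, 1), (c1 + c2) / 2, tolerance = 1e-9)
  expect_error(simulateIsotopeEnvelope(5, rep(0.1, 5), 500, 0), "charge")
})

test_that("titrations hit baseline, midpoint, and plateau", {
  d0 <- 6.34; dD <- -2.61; ec50 <- 2.2
  ts <- hyperbolicTitration(d0, dD, ec50, c(0, ec50, 1e4 * ec50),
                            deltaAt = "asymptote")
  u <- titrationPoints(ts)$uptake
  expect_equal(u[1], d0)
  expect_equal(u[2], d0 + dD / 2, tolerance = 1e-12)
  expect_equal(u[3], d0 + dD, tolerance = abs(dD) * 1e-3)
  expect_error(hyperbolicTitration(1, -1, 1, numeric(0)), "empty")

  # mechanistic titration: zero ligand equals the apo baseline
  sys <- uniformSystem(logP = 2, rate = 0.01)
  cpl <- ligandCoupling(0.65, rep(2, nchar(sys@protein@sequence)))
  mts <- simulateTitration(sys, cpl, c(2, 11), c(0, 0.65, 25), noiseSd = 0)
  apo <- records(simulatePeptideUptake(sys, data.frame(start = 2, end = 11),
                                       5400))
  expect_equal(titrationPoints(mts)$uptake[1], apo$mt - apo$m0,
               tolerance = 1e-12)
  expect_error(simulateTitration(sys, cpl, c(2, 11), numeric(0)), "empty")
})

test_that("slow-mode mixtures are theta-linear; fast mode converges to them
           as the protection increment vanishes", {
  sys <- uniformSystem(logP = 1, rate = 1e-4)  # mid-curve at 90 min
  n <- nchar(sys@protein@sequence)
  # slow mode: mixture uptake is linear in theta
  cpl <- ligandCoupling(1, rep(2, n), mode = "slow_two_population")
  up <- function(theta) {
    D <- simulateResidueExchange(sys, 5400, theta, cpl)
    rep_idx <- 4:11
    D$weights[1] * sum(D$free[rep_idx, 1]) +
      D$weights[2] * sum(D$bound[rep_idx, 1])
  }
  expect_equal(up(0.5), (up(0) + up(1)) / 2, tolerance = 1e-12)

  # fast-mode centroid approaches the slow-mode mixture as delta ln P -> 0
  gap <- vapply(c(1, 0.5, 0.2, 0.05, 0.01), function(d) {
    cf <- ligandCoupling(1, rep(d, n), mode = "fast_exchange")
    cs <- ligandCoupling(1, rep(d, n), mode = "slow_two_population")
    Df <- simulateResidueExchange(sys, 5400, 0.5, cf)
    Ds <- simulateResidueExchange(sys, 5400, 0.5, cs)
    mix <- Ds$weights[1] * Ds$free + Ds$weights[2] * Ds$bound
    max(abs(Df - mix))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 1e-6)
})

test_that("proteolysis decay generator matches half-life arithmetic", {
  still <- proteolysisModel(0, noiseSd = 0)
  expect_true(all(timecoursePoints(simulateProteolysis(still))$fraction == 1))
  m <- proteolysisModel(log(2), noiseSd = 0, timepoints = c(0.5, 1, 2))
  f <- timecoursePoints(simulateProteolysis(m))$fraction
  expect_equal(f[2], 0.5, tolerance = 1e-12)
  bound <- proteolysisModel(log(2), rateBound = 0, noiseSd = 0,
                            timepoints = c(1, 2))
  expect_equal(
    timecoursePoints(simulateProteolysis(bound, withLigand = TRUE))$fraction,
    c(1, 1))
})

test_that("occupancy models agree in the dilute-protein limit", {
  L <- c(0.1, 0.65, 2, 25)
  hyp <- thetaOccupancy(L, 0.65)
  quad <- thetaOccupancy(L, 0.65, "quadratic_depletion", proteinTotal = 1e-8)
  expect_equal(quad, hyp, tolerance = 1e-6)
  # with appreciable protein, depletion lowers occupancy at low ligand
  quad2 <- thetaOccupancy(L, 0.65, "quadratic_depletion", proteinTotal = 0.25)
  expect_true(all(quad2 <= hyp + 1e-12))
})
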