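test_that("exponential refits are exact on noiseless decays", {
  tc <- ProteolysisTimecourse(protein = "p", condition = "vehicle",
                              points = data.frame(time = c(0.5, 1, 2, 4, 8, 24),
                                                  fraction = exp(-0.2 * c(0.5, 1, 2, 4, 8, 24))))
  fit <- fitExponentialDecay(tc)@fit
  expect_true(fit$converged)
  expect_equal(fit$rate, 0.2, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
})

test_that("constant and rising timecourses are handled, not fatal", {
  flat <- ProteolysisTimecourse(protein = "p", condition = "vehicle",
                                points = data.frame(time = c(1, 2, 4, 8),
                                                    fraction = rep(1, 4)))
  expect_equal(fitExponentialDecay(flat)@fit$rate, 0, tolerance = 1e-9)

  rising <- ProteolysisTimecourse(protein = "p", condition = "vehicle",
                                  points = data.frame(time = c(1, 2, 4, 8),
                                                      fraction = c(0.2, 0.4, 0.6, 0.9)))
  expect_false(fitExponentialDecay(rising)@fit$converged)

  two <- ProteolysisTimecourse(protein = "p", condition = "vehicle",
                               points = data.frame(time = c(1, 2),
                                                   fraction = c(1, 0.5)))
  expect_error(fitExponentialDecay(two), ">= 3 timepoints")
})

test_that("timecourse AUC matches closed forms", {
  mk <- function(t, f) ProteolysisTimecourse(protein = "p",
                                             condition = "vehicle",
                                             points = data.frame(time = t,
                                                                 fraction = f))
  expect_equal(timecourseAUC(mk(c(0, 24), c(1, 1))), 24)
  expect_equal(timecourseAUC(mk(c(0, 24), c(1, 0))), 12)
  t <- seq(0, 24, by = 0.01); k <- 0.3
  expect_equal(timecourseAUC(mk(t, exp(-k * t))),
               (1 - exp(-k * 24)) / k, tolerance = 1e-4)
  # inserting a collinear interior point does not change the area
  expect_equal(timecourseAUC(mk(c(0, 12, 24), c(1, 0.5, 0))),
               timecourseAUC(mk(c(0, 24), c(1, 0))))
  expect_error(timecourseAUC(mk(5, 0.5)), ">= 2 timepoints")
})

test_that("single-timepoint protection is a plain signed difference", {
  expect_equal(protectionSingleTimepoint(0.2, 0.8), 0.6)
  expect_equal(protectionSingleTimepoint(0.5, 0.5), 0)
  expect_equal(protectionSingleTimepoint(0.8, 0.2),
               -protectionSingleTimepoint(0.2, 0.8))
  expect_error(protectionSingleTimepoint(-0.1, 0.5))
})

test_that("Pearson correlation matches the textbook formula", {
  x <- 1:5
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearsonCorrelation(x, -x)$r, -1, tolerance = 1e-12)
  # 9-point synthetic (proteolysis AUC, HDX AUC) table vs the covariance
  # formula computed from first principles
  px <- c(3.2, 7.8, 1.1, 12.4, 5.0, 9.9, 2.2, 6.1, 8.4)
  py <- c(150, 210, 130, 260, 170, 240, 120, 205, 195)
  byHand <- sum((px - mean(px)) * (py - mean(py))) /
    sqrt(sum((px - mean(px))^2) * sum((py - mean(py))^2))
  got <- pearsonCorrelation(px, py)
  expect_equal(got$r, byHand, tolerance = 1e-10)
  tstat <- byHand * sqrt((9 - 2) / (1 - byHand^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tstat), df = 7), tolerance = 1e-10)
  # pairwise deletion of missing entries
  expect_equal(pearsonCorrelation(c(px, NA), c(py, 1))$r, byHand,
               tolerance = 1e-12)
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "3 complete")
})

test_that("correlation is invariant under affine rescaling up to sign", {
  withr::with_seed(11, {
    x <- rnorm(9); y <- rnorm(9)
    r0 <- pearsonCorrelation(x, y)$r
    expect_equal(pearsonCorrelation(3 * x + 2, 0.5 * y - 7)$r, r0,
                 tolerance = 1e-12)
    expect_equal(pearsonCorrelation(-3 * x + 2, y)$r, -r0, tolerance = 1e-12)
  })
})

test_that("decay fits recover rates across the noisy parameter sweep", {
  # duplicate timecourses on a dense 24 h grid, averaged before fitting
  tp <- c(1 / 60, 0.1, 0.25, 0.5, 1, 2, 3, 5, 8, 12, 16, 24)
  errs <- vapply(1:200, function(i) {
    k <- withr::with_seed(1000L + i, runif(1, 0.05, 2))
    m <- proteolysisModel(k, noiseSd = 0.05, timepoints = tp)
    a <- timecoursePoints(simulateProteolysis(m, seed = 2000L + i))$fraction
    b <- timecoursePoints(simulateProteolysis(m, seed = 7000L + i))$fraction
    tc <- ProteolysisTimecourse(protein = "p", condition = "vehicle",
                                points = data.frame(time = tp,
                                                    fraction = (a + b) / 2))
    fit <- fitExponentialDecay(tc)@fit
    abs(fit$rate - k) / k
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_lt(mean(errs > 0.25), 0.02)   # no gross failures
})

test_that("stability comparisons join metrics by protein name", {
  px <- stats::setNames(c(3.2, 7.8, 1.1, 12.4, 5.0), paste0("p", 1:5))
  py <- stats::setNames(c(150, 210, 130, 260, 170), paste0("p", 1:5))
  sc <- stabilityComparison(px, py, xlab = "proteolysis AUC",
                            ylab = "HDX AUC")
  expect_s4_class(sc, "StabilityComparison")
  expect_equal(sc@r, pearsonCorrelation(px, py)$r)
  expect_identical(nrow(sc@metrics), 5L)
  expect_error(stabilityComparison(unname(px), py), "name")
})
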