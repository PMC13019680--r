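test_that("exposure generation is reproducible and respects the correlation design", {
  cfg <- simConfig(nSubjects = 200, seed = 42)
  p1 <- generateExposures(cfg)
  p2 <- generateExposures(cfg)
  expect_identical(concMatrix(p1, "t18"), concMatrix(p2, "t18"))
  expect_identical(concMatrix(p1, "t34"), concMatrix(p2, "t34"))

  # independence design: no cross-chemical, no cross-visit correlation
  cfg0 <- simConfig(nSubjects = 5000, rhoWithin = 0, rhoBetween = 0,
                    crossGroupPairs = NULL, icc = 0, lodQuantile = 0,
                    seed = 7)
  p0 <- generateExposures(cfg0)
  lg <- log2(t(concMatrix(p0, "t18")))
  cm <- cor(lg)
  offdiag <- cm[upper.tri(cm)]
  expect_lt(max(abs(offdiag)), 0.1)
})

test_that("icc = 1 makes the two visits identical; lodQuantile sets the censoring rate", {
  cfg1 <- simConfig(nSubjects = 100, icc = 1, lodQuantile = 0, seed = 3)
  p <- generateExposures(cfg1)
  # identical up to eigendecomposition round-off in the PSD factorization
  expect_equal(concMatrix(p, "t18"), concMatrix(p, "t34"),
               tolerance = 1e-6)

  cfg4 <- simConfig(nSubjects = 5000, lodQuantile = 0.4, seed = 8)
  p4 <- generateExposures(cfg4)
  ndRate <- rowMeans(!detectedMatrix(p4, "t18"))
  expect_true(all(abs(ndRate - 0.4) < 0.03))
})

test_that("log-scale marginals are calibrated to the generating parameters", {
  cfg <- simConfig(nSubjects = 5000, lodQuantile = 0, seed = 12)
  p <- generateExposures(cfg)
  lg <- log2(concMatrix(p, "t18"))
  mns <- rowMeans(lg)
  sds <- apply(lg, 1, sd)
  mcse_m <- cfg@logGSD / sqrt(5000)
  expect_true(all(abs(mns - cfg@logMedian) < 3 * mcse_m))
  expect_true(all(abs(sds - cfg@logGSD) < 3 * cfg@logGSD / sqrt(2 * 4999)))
})

test_that("covariates are complete, deterministic, and sex-balanced", {
  cv <- generateCovariates(10, seed = 1)
  expect_equal(nrow(cv), 10)
  expect_false(anyNA(cv))
  expect_identical(cv, generateCovariates(10, seed = 1))
  big <- generateCovariates(5000, seed = 2)
  expect_lt(abs(mean(big$sex == "male") - 0.5), 0.02)
})

test_that("outcome generation matches the WQS mean structure", {
  cfg <- tinyConfig(n = 50, seed = 9, lodQuantile = 0)
  # degenerate: all effects and noise zero -> constant intercept
  t0 <- simTruth(cfg, alpha = 1.5, sigma = 0)
  panel <- generateExposures(cfg)
  y0 <- generateOutcome(panel, NULL, t0, seed = 9)
  expect_equal(unname(y0), rep(1.5, 50))

  # weight concentration: noiseless single active chemical -> exact affine
  t1 <- simTruth(cfg, alpha = 0.2, beta = c(LMWP = 0.7),
                 weights = list(LMWP = c(1, 0, 0)), sigma = 0)
  y1 <- generateOutcome(panel, NULL, t1, seed = 9)
  qs <- quantileRank(panel)  # lodQuantile = 0: no missing cells
  expect_equal(unname(y1), 0.2 + 0.7 * unname(qs@scores[, "MEP"]))
})

test_that("regressing the outcome on the true index recovers the generating slope", {
  cfg <- simConfig(nSubjects = 5000, seed = 21, lodQuantile = 0)
  truth <- simTruth(cfg, beta = c(OP = 0.4), sigma = 0.5)
  panel <- generateExposures(cfg)
  y <- generateOutcome(panel, NULL, truth, seed = 21)
  qs <- quantileRank(panel)
  idx <- qs@scores[, names(truth@weights$OP)] %*% truth@weights$OP
  slope <- coef(lm(y ~ idx))[2]
  expect_lt(abs(slope - 0.4), 0.05)
})

test_that("repeated outcomes share a subject intercept with the requested variance split", {
  cfg <- tinyConfig(n = 40, seed = 4)
  truth <- simTruth(cfg, sigma = 0)
  panel <- generateExposures(cfg)
  r0 <- generateRepeatedOutcomes(panel, NULL, truth, nVisits = 3,
                                 subjectSD = 0, seed = 4)
  ymat <- matrix(r0$y, ncol = 3)
  expect_equal(ymat[, 1], ymat[, 2])
  expect_equal(ymat[, 1], ymat[, 3])

  cfg2 <- simConfig(nSubjects = 2000, seed = 14)
  truth2 <- simTruth(cfg2, sigma = 1)
  panel2 <- generateExposures(cfg2)
  r <- generateRepeatedOutcomes(panel2, NULL, truth2, nVisits = 2,
                                subjectSD = 1, seed = 14)
  ym <- matrix(r$y, ncol = 2)
  # var split 1:1 between subject and residual -> within-subject cor 0.5
  expect_lt(abs(cor(ym[, 1], ym[, 2]) - 0.5), 0.05)

  rv <- generateRepeatedOutcomes(panel2, NULL, truth2, nVisits = 2,
                                 visitEffects = c(0, 0.3),
                                 subjectSD = 0.5, seed = 15)
  yv <- matrix(rv$y, ncol = 2)
  expect_lt(abs(mean(yv[, 2] - yv[, 1]) - 0.3), 0.05)
})

test_that("mediation triplets follow the configured causal chain", {
  cfg <- tinyConfig(seed = 2)
  tNull <- simTruth(cfg, aPath = 0, bPath = 0.4, direct = 0.1)
  tri <- generateMediationTriplet(5000, tNull, seed = 2)
  expect_lt(abs(cov(tri$index, tri$mediator)), 0.05)

  tDet <- simTruth(cfg, aPath = 0.5, bPath = 0.4, direct = -0.1)
  det <- generateMediationTriplet(100, tDet, seed = 3,
                                  mediatorSD = 0, outcomeSD = 0)
  expect_equal(det$outcome, -0.1 * det$index + 0.4 * det$mediator)
  expect_equal(det$mediator, 0.5 * det$index)

  tri2 <- generateMediationTriplet(5000, tDet, seed = 4)
  a <- coef(lm(mediator ~ index, tri2))[2]
  b <- coef(lm(outcome ~ mediator + index, tri2))[2]
  expect_lt(abs(a * b - 0.2), 0.03)
})

test_that("reference charts tabulate the requested curves and enforce their invariants", {
  ch <- makeReferenceChart(c(20, 40), medianFun = function(g) 100 * g,
                           sdFun = function(g) rep(50, length(g)))
  expect_equal(length(ch@ga), 21)
  expect_true(all(diff(ch@ga) > 0))
  expect_equal(ch@median, 100 * ch@ga)
  expect_equal(ch@sd, rep(50, 21))
  expect_true(all(makeReferenceChart(c(12, 42))@sd > 0))
  expect_error(makeReferenceChart(c(5, 40)))
  # invariants rejected at construction
  expect_error(new("ReferenceChart", ga = c(20, 20), median = c(1, 2),
                   sd = c(1, 1)))
  expect_error(new("ReferenceChart", ga = c(20, 21), median = c(1, 2),
                   sd = c(1, -1)))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simConfig(nSubjects = 10, rhoWithin = 1.2, seed = 1))
  expect_error(simConfig(nSubjects = 10, lodQuantile = 1, seed = 1))
  # rho_between > rho_within on every pair makes the block matrix indefinite
  expect_error(simConfig(nSubjects = 10, rhoWithin = 0.05, rhoBetween = 0.9,
                         crossGroupPairs = NULL, seed = 1))
  expect_error(simTruth(simConfig(nSubjects = 10, seed = 1),
                        weights = list(LMWP = c(2, -1, 0))))
})
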