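# Small cohorts and quick sampler settings shared across test files.

tinyConfig <- function(n = 60, seed = 1, ...) {
  simConfig(nSubjects = n, seed = seed, ...)
}

# a minimal two-group panel built by hand (no randomness)
handPanel <- function() {
  conc <- matrix(c(1, 2, 4, 8,
                   3, 1, 2, 6,
                   2, 2, 2, 2,
                   5, 4, 3, 1), nrow = 4, byrow = TRUE,
                 dimnames = list(c("a1", "a2", "b1", "b2"),
                                 c("S1", "S2", "S3", "S4")))
  ExposureExperiment(list(t18 = conc),
                     lod = c(a1 = 0.1, a2 = 0.1, b1 = 0.1, b2 = 0.1),
                     groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
}

# short-chain fit for tests whose point is not convergence monitoring;
# diagnostics warnings from the reduced chain length are suppressed
quickFit <- function(design, seed, ...) {
  suppressWarnings(
    fitLbwqsr(design, chains = 2, warmup = 400, iter = 400, seed = seed, ...))
}

# design built from a simulated cohort; returns list(design, truth, ...)
simDesign <- function(n, seed, beta, weights = list(), sigma = 0.5,
                      covariates = FALSE) {
  cfg <- simConfig(nSubjects = n, seed = seed)
  truth <- simTruth(cfg, beta = beta, weights = weights, sigma = sigma)
  panel <- generateExposures(cfg)
  cov <- if (covariates) generateCovariates(n, seed = seed) else NULL
  y <- generateOutcome(panel, cov, truth, seed = seed)
  qs <- quantileRank(imputeBelowLOD(panel, seed = seed))
  list(design = buildDesign(qs, chemGroups(panel), cov, outcome = y),
       truth = truth, panel = panel, scores = qs, covariates = cov, y = y)
}
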