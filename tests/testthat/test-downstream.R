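test_that("mixture index is the weighted sum of log2 concentrations", {
  p <- log2Transform(handPanel())
  lg <- t(concMatrix(p, "t18"))
  w1 <- c(a1 = 1, a2 = 0)
  expect_equal(as.numeric(mixtureIndex(w1, p)), unname(lg[, "a1"]))
  wEq <- c(a1 = 0.5, a2 = 0.5)
  expect_equal(as.numeric(mixtureIndex(wEq, p)),
               unname(rowMeans(lg[, c("a1", "a2")])))
  set.seed(60)
  w <- runif(4); w <- setNames(w / sum(w), colnames(lg))
  oracle <- vapply(seq_len(nrow(lg)), function(i) sum(w * lg[i, names(w)]),
                   numeric(1))
  expect_equal(as.numeric(mixtureIndex(w, p)), oracle)
  expect_error(mixtureIndex(c(zz = 1), p), "absent")
  expect_error(mixtureIndex(c(a1 = 0.7, a2 = 0.7), p), "sum to 1")
})

test_that("sex interaction test recovers stratified slopes and the OLS identity", {
  set.seed(61)
  n <- 2000
  idx <- rnorm(n)
  sex <- factor(sample(c("female", "male"), n, TRUE))
  y <- ifelse(sex == "male", 0.5, -0.5) * idx + rnorm(n, 0, 0.5)
  r <- sexInteractionTest(idx, sex, y)
  expect_lt(r$pInteraction, 1e-3)
  expect_lt(abs(r$slopes[["male"]] - 0.5), 0.1)
  expect_lt(abs(r$slopes[["female"]] + 0.5), 0.1)
  # the product coefficient equals the difference of stratified slopes
  expect_equal(r$interaction, r$slopes[["male"]] - r$slopes[["female"]],
               tolerance = 1e-10)
  expect_error(sexInteractionTest(idx, factor(rep("male", n)), y),
               "both sexes")
})

test_that("single-pollutant association matches closed-form least squares", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1.2, 1.9, 3.4, 3.9, 5.1, 5.8)
  r <- singlePollutantAssoc(x, y)
  X <- cbind(1, x)
  bhat <- solve(t(X) %*% X, t(X) %*% y)  # normal equations oracle
  expect_equal(unname(r["beta"]), unname(bhat[2, 1]), tolerance = 1e-12)
  s2 <- sum((y - X %*% bhat)^2) / 4
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(unname(r["se"]), se, tolerance = 1e-12)

  rn <- suppressWarnings(singlePollutantAssoc(x, 2 * x))  # perfect fit
  expect_equal(unname(rn["beta"]), 2, tolerance = 1e-12)
  expect_lt(unname(rn["ciHigh"] - rn["ciLow"]), 1e-8)

  expect_error(singlePollutantAssoc(x, y, data.frame(dup = x)),
               "aliased")
})

test_that("null single-pollutant associations stay within 3 standard errors", {
  set.seed(62)
  hits <- vapply(1:300, function(i) {
    x <- rnorm(300); y <- rnorm(300)
    r <- singlePollutantAssoc(x, y)
    abs(r["beta"]) < 3 * r["se"]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("mediation decomposition is exact when the outcome equation is noiseless", {
  cfg <- tinyConfig(seed = 63)
  truth <- simTruth(cfg, aPath = 0.5, bPath = 0.4, direct = -0.1)
  # exogenous mediator disturbance keeps the outcome model identified;
  # the noiseless outcome equation makes b and the direct effect exact
  tri <- generateMediationTriplet(200, truth, seed = 63,
                                  mediatorSD = 1, outcomeSD = 0)
  m <- mediate(tri$index, tri$mediator, tri$outcome, nBoot = 200, seed = 1)
  expect_equal(unname(m@estimates["bPath"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(m@estimates["ade"]), -0.1, tolerance = 1e-12)
  expect_equal(unname(m@estimates["acme"]),
               unname(m@estimates["aPath"]) * 0.4, tolerance = 1e-12)

  # a fully deterministic chain collapses mediator onto exposure:
  # the decomposition is unidentified and must say so
  det <- generateMediationTriplet(200, truth, seed = 63,
                                  mediatorSD = 0, outcomeSD = 0)
  expect_error(mediate(det$index, det$mediator, det$outcome,
                       nBoot = 100, seed = 1), "collinear")
})

test_that("acme + ade equals the total-effect OLS coefficient exactly", {
  set.seed(64)
  for (rep in 1:5) {
    n <- 150
    x <- rnorm(n)
    med <- 0.4 * x + rnorm(n)
    y <- 0.3 * x + 0.5 * med + rnorm(n)
    cov <- data.frame(c1 = rnorm(n), c2 = factor(sample(letters[1:3], n, TRUE)))
    m <- mediate(x, med, y, cov, nBoot = 100, seed = rep)
    totalOLS <- coef(lm(y ~ x + c1 + c2, data = cbind(cov, x = x, y = y)))["x"]
    expect_lt(abs(m@estimates["acme"] + m@estimates["ade"] - totalOLS), 1e-10)
  }
})

test_that("bootstrap mediation is calibrated, convergent and reproducible", {
  cfg <- tinyConfig(seed = 65)
  # null a-path: ACME interval should cover 0 in nearly all replicates
  tNull <- simTruth(cfg, aPath = 0, bPath = 0.4, direct = 0.2)
  cover <- vapply(1:20, function(s) {
    tri <- generateMediationTriplet(300, tNull, seed = 100 + s)
    m <- mediate(tri$index, tri$mediator, tri$outcome, nBoot = 200,
                 seed = s)
    m@ci["acme", 1] <= 0 && m@ci["acme", 2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # proportion mediated converges to a*b / (a*b + direct)
  tAlt <- simTruth(cfg, aPath = 0.5, bPath = 0.4, direct = 0.3)
  tri <- generateMediationTriplet(5000, tAlt, seed = 66)
  m <- mediate(tri$index, tri$mediator, tri$outcome, nBoot = 500, seed = 66)
  expect_lt(abs(m@estimates["propMediated"] - 0.2 / 0.5), 0.05)

  m2 <- mediate(tri$index, tri$mediator, tri$outcome, nBoot = 500, seed = 66)
  expect_identical(m@ci, m2@ci)
  expect_identical(m@pValue, m2@pValue)
  expect_error(mediate(tri$index, rep(1, 5000), tri$outcome, nBoot = 100,
                       seed = 1), "constant")
})
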