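test_that("design assembly aligns groups, expands contrasts and drops incomplete rows", {
  p <- handPanel()
  qs <- quantileRank(p)
  des <- buildDesign(qs, chemGroups(p), outcome = c(1, 2, 3, 4))
  expect_equal(nlevels(des@groups), 2)
  expect_equal(as.integer(table(des@groups)), c(2L, 2L))
  expect_equal(ncol(des@Z), 0)

  cov <- data.frame(g3 = factor(c("a", "b", "c", "a")), x = 1:4)
  des2 <- buildDesign(qs, chemGroups(p), cov, outcome = c(1, 2, 3, 4))
  expect_equal(ncol(des2@Z), 3)  # 2 indicators + 1 numeric
  expect_equal(sum(grepl("^g3", colnames(des2@Z))), 2)

  expect_message(
    des3 <- buildDesign(qs, chemGroups(p), outcome = c(1, NA, 3, 4)),
    "1 incomplete")
  expect_equal(length(des3@y), 3)

  expect_error(buildDesign(qs, c(a1 = "A", a2 = "A", b1 = "B"),
                           outcome = c(1, 2, 3, 4)),
               "missing from the group map")
})

test_that("the analytic gradient matches finite differences in all model variants", {
  set.seed(50)
  n <- 30; gsize <- c(3L, 1L, 2L); J <- 6L; K <- 2L; S <- 6L
  Q <- matrix(sample(0:3, n * J, TRUE), n, J)
  Z <- matrix(rnorm(n * K), n, K)
  y <- rnorm(n)
  subj <- sample.int(S, n, TRUE) - 1L
  hyper <- list(sd_alpha = 10, sd_gamma = 10, sigma_scale = 5,
                sigma_u_scale = 1)
  wfix <- unlist(lapply(gsize, function(j) rep(1 / j, j)))
  for (cse in list(list(pt = 0L, fw = FALSE, S = S, lam = 0.5, a0 = 1),
                   list(pt = 0L, fw = FALSE, S = 0L, lam = 1, a0 = 2),
                   list(pt = 1L, fw = FALSE, S = 0L, lam = 0.5, a0 = 1),
                   list(pt = 0L, fw = TRUE, S = 0L, lam = 0, a0 = 1))) {
    subj_ <- if (cse$S > 0) subj else integer(0)
    V <- if (cse$fw) 0L else J - 3L
    d <- 1L + 3L + K + V + (if (cse$pt == 0L) 1L else 0L) + 1L +
      (if (cse$S > 0) 1L + cse$S else 0L)
    th <- rnorm(d, 0, 0.4)
    lp <- function(t) mixBWQS:::.lbwqsrLpGrad(t, y, Q, Z, gsize, subj_,
                                              cse$S, cse$pt, cse$lam,
                                              cse$a0, cse$fw, wfix, hyper)
    g <- lp(th)$grad
    gn <- vapply(seq_len(d), function(i) {
      e <- rep(0, d); e[i] <- 1e-6
      (lp(th + e)$lp - lp(th - e)$lp) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-5)
  }
})

test_that("a single-chemical group reduces to ordinary Bayesian regression on its score", {
  set.seed(51)
  n <- 300
  q <- sample(0:3, n, TRUE)
  y <- 0.5 + 0.4 * q + rnorm(n, 0, 0.5)
  Q <- matrix(q, n, 1, dimnames = list(NULL, "solo"))
  des <- buildDesign(Q, c(solo = "G"), outcome = y)
  fit <- quickFit(des, seed = 51, prior = "flat")
  # the one weight is the point mass 1
  expect_true(all(posteriorDraws(fit, "w[solo]") == 1))
  ols <- coef(lm(y ~ q))
  bdraws <- posteriorDraws(fit, "beta[G]")
  mcse <- sd(bdraws) / sqrt(mixBWQS:::.essTotal(
    fit@draws[, , "beta[G]", drop = TRUE]))
  expect_lt(abs(mean(bdraws) - ols[2]), max(3 * mcse, 0.01))
})

test_that("the posterior is invariant to rescaling raw concentrations", {
  sim <- simDesign(n = 80, seed = 52, beta = c(LMWP = 0.4))
  panel2 <- sim$panel
  for (tp in timePoints(panel2)) {
    SummarizedExperiment::assay(panel2, tp) <-
      SummarizedExperiment::assay(panel2, tp) * 1000
  }
  SummarizedExperiment::rowData(panel2)$lod <-
    SummarizedExperiment::rowData(panel2)$lod * 1000
  qs2 <- quantileRank(imputeBelowLOD(panel2, seed = 52))
  expect_identical(sim$scores@scores, qs2@scores)
  des2 <- buildDesign(qs2, chemGroups(panel2), outcome = sim$y)
  f1 <- suppressWarnings(
    fitLbwqsr(sim$design, chains = 1, warmup = 150, iter = 150, seed = 52))
  f2 <- suppressWarnings(
    fitLbwqsr(des2, chains = 1, warmup = 150, iter = 150, seed = 52))
  expect_identical(f1@draws, f2@draws)
})

test_that("with weights fixed at truth and a flat prior the fit matches OLS on known indices", {
  sim <- simDesign(n = 400, seed = 53, beta = c(LMWP = 0.5, OP = -0.3),
                   weights = list(LMWP = c(0.6, 0.3, 0.1)))
  truth <- sim$truth
  fit <- suppressWarnings(
    fitLbwqsr(sim$design, prior = "flat", fixedWeights = truth@weights,
              chains = 2, warmup = 500, iter = 500, seed = 53))
  idx <- sapply(names(truth@beta), function(g)
    sim$scores@scores[, names(truth@weights[[g]])] %*% truth@weights[[g]])
  ols <- coef(lm(sim$y ~ idx))[-1]
  for (k in seq_along(truth@beta)) {
    g <- names(truth@beta)[k]
    d <- posteriorDraws(fit, paste0("beta[", g, "]"))
    mcse <- sd(d) / sqrt(mixBWQS:::.essTotal(
      fit@draws[, , paste0("beta[", g, "]"), drop = TRUE]))
    expect_lt(abs(mean(d) - ols[k]), 2 * max(mcse, 5e-3))
  }
})

test_that("elastic-net shrinkage tightens null-group posteriors relative to a flat prior", {
  sim <- simDesign(n = 250, seed = 54, beta = c(LMWP = 0.5))
  fEnet <- quickFit(sim$design, seed = 54)
  fFlat <- quickFit(sim$design, seed = 54, prior = "flat")
  nulls <- setdiff(levels(sim$design@groups), "LMWP")
  sdE <- vapply(nulls, function(g)
    sd(posteriorDraws(fEnet, paste0("beta[", g, "]"))), numeric(1))
  sdF <- vapply(nulls, function(g)
    sd(posteriorDraws(fFlat, paste0("beta[", g, "]"))), numeric(1))
  expect_true(mean(sdE < sdF) >= 6 / 7)
  expect_lt(mean(sdE / sdF), 1)
})

test_that("posterior summaries respect the simplex and interval invariants", {
  sim <- simDesign(n = 120, seed = 55, beta = c(PHENOL = 0.4))
  fit <- quickFit(sim$design, seed = 55)
  sm <- summarizePosterior(fit)
  expect_true(all(sm$cri_low <= sm$cri_high))
  wt <- attr(sm, "weights")
  for (g in names(wt)) expect_equal(sum(wt[[g]]), 1, tolerance = 1e-8)
  # every stored weight draw lies on the simplex
  pn <- dimnames(fit@draws)[[3]]
  for (g in levels(fit@groups)) {
    chems <- names(fit@groups)[fit@groups == g]
    wsum <- apply(fit@draws[, , paste0("w[", chems, "]"), drop = FALSE],
                  c(1, 2), sum)
    expect_true(all(abs(wsum - 1) < 1e-8))
    expect_true(all(fit@draws[, , paste0("w[", chems, "]")] >= 0))
  }
})

test_that("the sampler agrees with an independent Gibbs implementation (JAGS)", {
  skip_if_not_installed("rjags")
  set.seed(99)
  n <- 150
  Q <- matrix(sample(0:3, n * 4, TRUE), n, 4,
              dimnames = list(NULL, c("c1", "c2", "c3", "c4")))
  y <- as.numeric(1 + 0.5 * (Q[, 1:2] %*% c(0.7, 0.3)) -
                    0.3 * (Q[, 3:4] %*% c(0.5, 0.5)) + rnorm(n, 0, 0.5))
  des <- buildDesign(Q, c(c1 = "A", c2 = "A", c3 = "B", c4 = "B"),
                     outcome = y)
  fit <- suppressWarnings(
    fitLbwqsr(des, chains = 2, warmup = 800, iter = 1500, seed = 99))

  jm <- "
  model {
    for (i in 1:n) { y[i] ~ dnorm(alpha + inprod(Q[i,], wb[]), prec) }
    for (j in 1:J) {
      wr[j] ~ dgamma(1, 1)
      w[j] <- wr[j] / sg[grp[j]]
      wb[j] <- beta[grp[j]] * w[j]
    }
    for (g in 1:G) {
      sg[g] <- inprod(Gmat[g,], wr[])
      beta[g] ~ dnorm(0, 1e-4)
      zero[g] ~ dpois(phi[g])
      phi[g] <- 0.5 * abs(beta[g]) / tau + 0.5 * beta[g]^2 / (2 * tau^2) +
                log(tau) + 30 + betadens[g]
      betadens[g] <- logdensity.norm(beta[g], 0, 1e-4)
    }
    tau ~ dt(0, 1, 1) T(0,)
    alpha ~ dnorm(0, 0.01)
    sigma ~ dnorm(0, 0.04) T(0,)
    prec <- 1 / sigma^2
  }"
  jags <- rjags::jags.model(
    textConnection(jm),
    data = list(y = y, Q = Q, n = n, J = 4, G = 2,
                grp = c(1, 1, 2, 2),
                Gmat = rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
                zero = c(0, 0)),
    n.chains = 2, n.adapt = 1000, quiet = TRUE)
  samp <- rjags::coda.samples(jags, c("alpha", "beta", "w", "sigma"), 4000)
  js <- summary(samp)$statistics
  expect_lt(abs(mean(posteriorDraws(fit, "beta[A]")) - js["beta[1]", "Mean"]),
            3 * js["beta[1]", "SD"] / sqrt(200) + 0.01)
  expect_lt(abs(mean(posteriorDraws(fit, "beta[B]")) - js["beta[2]", "Mean"]),
            3 * js["beta[2]", "SD"] / sqrt(200) + 0.01)
  expect_lt(abs(mean(posteriorDraws(fit, "w[c1]")) - js["w[1]", "Mean"]), 0.03)
  expect_lt(abs(mean(posteriorDraws(fit, "sigma")) - js["sigma", "Mean"]),
            0.02)
})

test_that("the repeated-outcome variant recovers variance components and falls back gracefully", {
  cfg <- simConfig(nSubjects = 250, seed = 56)
  truth <- simTruth(cfg, beta = c(LMWP = 0.3), sigma = 0.5)
  panel <- generateExposures(cfg)
  qs <- quantileRank(imputeBelowLOD(panel, seed = 56))
  rep0 <- generateRepeatedOutcomes(panel, NULL, truth, nVisits = 2,
                                   subjectSD = 0, seed = 56)
  fit0 <- suppressWarnings(
    fitTimeVarying(rep0, qs, chemGroups(panel),
                   chains = 2, warmup = 400, iter = 400, seed = 56))
  expect_lt(median(posteriorDraws(fit0, "sigma_u")), 0.15)

  single <- rep0[rep0$visit == "v1", ]
  w <- capture_warnings(
    fs <- fitTimeVarying(single, qs, chemGroups(panel),
                         chains = 1, warmup = 200, iter = 200, seed = 56))
  expect_true(any(grepl("single-visit", w)))
  expect_false("sigma_u" %in% dimnames(fs@draws)[[3]])
})
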