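test_that("below-LOD imputation fills every censored cell strictly inside (0, LOD)", {
  p <- handPanel()  # no non-detects
  expect_identical(concMatrix(imputeBelowLOD(p, seed = 1), "t18"),
                   concMatrix(p, "t18"))

  cfg <- simConfig(nSubjects = 400, lodQuantile = 0.3, seed = 5)
  panel <- generateExposures(cfg)
  imp <- imputeBelowLOD(panel, seed = 5)
  for (tp in timePoints(imp)) {
    conc <- concMatrix(imp, tp)
    det <- detectedMatrix(imp, tp)
    expect_false(anyNA(conc))
    filled <- conc[!det]
    lods <- matrix(chemLOD(imp), nrow(conc), ncol(conc))[!det]
    expect_true(all(filled > 0 & filled < lods))
    # detected cells untouched
    expect_identical(conc[det], concMatrix(panel, tp)[det])
  }
  # reproducible under seed, sensitive to it
  expect_identical(concMatrix(imputeBelowLOD(panel, seed = 5), "t18"),
                   concMatrix(imp, "t18"))
  expect_false(identical(concMatrix(imputeBelowLOD(panel, seed = 6), "t18"),
                         concMatrix(imp, "t18")))
})

test_that("truncated-log-normal imputation matches direct tail sampling", {
  set.seed(31)
  n <- 2000
  x <- rlnorm(n, 0, 1)
  lod <- qlnorm(0.1, 0, 1)
  conc <- matrix(x, 1, n, dimnames = list("chem", paste0("S", 1:n)))
  det <- conc >= lod
  conc[!det] <- NA
  p <- ExposureExperiment(list(t18 = conc), list(t18 = det),
                          lod = c(chem = lod), groups = c(chem = "G"))
  imp <- imputeBelowLOD(p, seed = 77)
  imputed <- concMatrix(imp, "t18")[1, !det[1, ]]
  # oracle: direct draws from the fitted log-normal truncated to (0, LOD),
  # with the fit recomputed here from the detected values
  obs <- x[x >= lod]
  mhat <- mean(log(obs)); shat <- sd(log(obs))
  pcap <- plnorm(lod, mhat, shat)
  oracle <- qlnorm(runif(5000) * pcap, mhat, shat)
  ks <- suppressWarnings(ks.test(imputed, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("log2 transformation is exact and rejects nonpositive cells", {
  p <- handPanel()
  lp <- log2Transform(p)
  expect_equal(concMatrix(lp, "t18")["a1", "S4"], 3)   # 8 -> 3
  expect_equal(concMatrix(lp, "t18")["a1", "S1"], 0)   # 1 -> 0
  conc <- matrix(40.4, 1, 4, dimnames = list("MEP", paste0("S", 1:4)))
  pm <- ExposureExperiment(list(t18 = conc), lod = c(MEP = 0.2),
                           groups = c(MEP = "LMWP"))
  expect_equal(concMatrix(log2Transform(pm), "t18")[1, 1], 5.33628,
               tolerance = 1e-5)
  m <- concMatrix(handPanel(), "t18"); m["b1", "S2"] <- NA
  bad <- ExposureExperiment(list(t18 = m),
                            lod = c(a1 = .1, a2 = .1, b1 = .1, b2 = .1),
                            groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_error(log2Transform(bad), "b1.*S2")
})

test_that("quartile scoring follows the cutpoint/tie rules and is uniform", {
  expect_equal(as.integer(quantileRank(c(1, 2, 3, 4))), c(0L, 1L, 2L, 3L))
  expect_equal(as.integer(quantileRank(rep(2.5, 6))), rep(3L, 6))
  expect_error(quantileRank(c(1, 2, 3)), "at least 4")

  set.seed(11)
  x <- rexp(1000)
  s <- quantileRank(x)
  freq <- table(factor(s, levels = 0:3)) / 1000
  expect_true(all(abs(freq - 0.25) < 0.05))
  cuts <- attr(s, "cutpoints")
  expect_equal(cuts, quantile(x, c(.25, .5, .75), names = FALSE))
})

test_that("quartile scores are invariant to strictly monotone transforms", {
  set.seed(12)
  x <- rlnorm(200)
  s <- as.integer(quantileRank(x))
  expect_identical(s, as.integer(quantileRank(log2(x))))
  expect_identical(s, as.integer(quantileRank(x^3)))
  expect_identical(s, as.integer(quantileRank(7 * x)))

  # panel route: impute + rank leaves no missing scores
  cfg <- simConfig(nSubjects = 100, lodQuantile = 0.2, seed = 13)
  qs <- quantileRank(imputeBelowLOD(generateExposures(cfg), seed = 13))
  expect_false(anyNA(qs@scores))
  expect_true(all(qs@scores %in% 0:3))
})

test_that("Spearman matrix is rank-based, symmetric and NA for degenerate chemicals", {
  set.seed(14)
  x <- rnorm(10)
  conc <- rbind(x = x, cube = x^3, neg = max(x) + 1 - x, z = rnorm(10))
  conc <- conc - min(conc) + 0.5
  rownames(conc) <- c("x", "cube", "neg", "z")
  colnames(conc) <- paste0("S", 1:10)
  p <- ExposureExperiment(list(t18 = conc),
                          lod = setNames(rep(.1, 4), rownames(conc)),
                          groups = setNames(rep("G", 4), rownames(conc)))
  sp <- spearmanMatrix(p)
  expect_equal(sp["x", "cube"], 1)
  expect_equal(sp["x", "neg"], -1)
  expect_equal(sp, t(sp))
  # oracle: Pearson correlation of average ranks
  oracle <- cor(rank(conc["x", ]), rank(conc["z", ]))
  expect_equal(sp["x", "z"], oracle)
  # rank-transform invariance of the whole matrix
  pr <- ExposureExperiment(list(t18 = t(apply(conc, 1, rank))),
                           lod = setNames(rep(.1, 4), rownames(conc)),
                           groups = setNames(rep("G", 4), rownames(conc)))
  expect_equal(spearmanMatrix(pr), sp)

  constRow <- conc; constRow["z", ] <- 1
  pc <- ExposureExperiment(list(t18 = constRow),
                           lod = setNames(rep(.1, 4), rownames(conc)),
                           groups = setNames(rep("G", 4), rownames(conc)))
  expect_true(is.na(spearmanMatrix(pc)["z", "x"]))
})

test_that("ICC equals the one-way ANOVA estimator and recovers the generating value", {
  # perfect repeatability
  conc <- matrix(rlnorm(10), 2, 5,
                 dimnames = list(c("c1", "c2"), paste0("S", 1:5)))
  p1 <- ExposureExperiment(list(t18 = conc, t34 = conc),
                           lod = c(c1 = .01, c2 = .01),
                           groups = c(c1 = "G", c2 = "G"))
  expect_equal(iccRepeatability(p1)$icc, c(1, 1))

  # 5-subject toy panel against an aov() oracle
  set.seed(15)
  v1 <- rlnorm(5); v2 <- rlnorm(5)
  m1 <- matrix(v1, 1, 5, dimnames = list("c", paste0("S", 1:5)))
  m2 <- matrix(v2, 1, 5, dimnames = list("c", paste0("S", 1:5)))
  p2 <- ExposureExperiment(list(t18 = m1, t34 = m2), lod = c(c = .01),
                           groups = c(c = "G"))
  res <- iccRepeatability(p2)
  long <- data.frame(y = log2(c(v1, v2)), s = factor(rep(1:5, 2)))
  ms <- summary(aov(y ~ s, data = long))[[1]][["Mean Sq"]]
  expect_equal(res$msb, ms[1])
  expect_equal(res$msw, ms[2])
  expect_equal(res$icc, (ms[1] - ms[2]) / (ms[1] + ms[2]))

  # exchangeability null: permuted second visit -> ICC near 0
  set.seed(16)
  n <- 800
  a <- rlnorm(n); b <- sample(a)
  pn <- ExposureExperiment(
    list(t18 = matrix(a, 1, n, dimnames = list("c", paste0("S", 1:n))),
         t34 = matrix(b, 1, n, dimnames = list("c", paste0("S", 1:n)))),
    lod = c(c = .01), groups = c(c = "G"))
  expect_lt(abs(iccRepeatability(pn)$icc), 0.08)

  # generating-parameter recovery at n = 2000
  cfg <- simConfig(nSubjects = 2000, icc = 0.45, lodQuantile = 0, seed = 17)
  icc <- iccRepeatability(generateExposures(cfg))
  expect_true(all(abs(icc$icc - 0.45) < 0.05))

  # flooring clamps negative estimates at zero
  expect_gte(iccRepeatability(pn, floorZero = TRUE)$icc, 0)
  expect_error(iccRepeatability(
    ExposureExperiment(list(t18 = m1), lod = c(c = .01),
                       groups = c(c = "G"))))
})
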