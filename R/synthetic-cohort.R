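# Default panel: 30 urinary metabolites in 8 mixture groups, the layout of
# a typical European pregnancy biomonitoring panel (phthalates, DINCH,
# insecticides, PAHs, organophosphates, phenols, parabens). log2 medians
# span roughly 0.5-40 ng/mL; geometric SDs 2-3; ICC values span the
# low-to-moderate reproducibility seen for nonpersistent chemicals.
.defaultChemicalTable <- function() {
  data.frame(
    chemical = c("MEHP", "MEHHP", "MEOHP", "MECPP", "MCMHP", "MBzP",
                 "cx-MiNP", "OH-MiNP", "oxo-MiNP",
                 "MEP", "MiBP", "MnBP",
                 "OH-MINCH", "cx-MINCH",
                 "TCPY", "3-PBA",
                 "1-NAP", "2-NAP", "1-OH-PYR", "9-PHOL",
                 "DMP", "DMTP", "DEP",
                 "BPA", "BPS", "OXBE", "TCS",
                 "MEPA", "ETPA", "PRPA"),
    group = rep(c("HMWP", "LMWP", "DINCH", "INSECT", "PAH", "OP",
                  "PHENOL", "PARABEN"),
                times = c(9, 3, 2, 2, 4, 3, 4, 3)),
    logMedian = log2(c(2.1, 6.5, 4.8, 7.9, 2.4, 3.1, 1.9, 2.6, 1.2,
                       40.4, 9.8, 11.3,
                       1.4, 1.8,
                       1.9, 0.6,
                       2.7, 4.1, 0.5, 0.8,
                       3.4, 2.3, 1.6,
                       1.5, 0.6, 1.1, 1.3,
                       15.4, 1.0, 2.8)),
    logGSD = c(1.25, 1.30, 1.28, 1.22, 1.35, 1.45, 1.30, 1.28, 1.32,
               1.60, 1.35, 1.30,
               1.40, 1.38,
               1.30, 1.45,
               1.35, 1.30, 1.50, 1.48,
               1.55, 1.60, 1.50,
               1.40, 1.55, 1.60, 1.65,
               1.60, 1.55, 1.58),
    icc = c(0.35, 0.40, 0.38, 0.42, 0.30, 0.28, 0.33, 0.36, 0.25,
            0.55, 0.45, 0.48,
            0.30, 0.32,
            0.20, 0.15,
            0.22, 0.25, 0.10, 0.12,
            0.18, 0.15, 0.20,
            0.25, 0.12, 0.50, 0.65,
            0.60, 0.45, 0.55),
    stringsAsFactors = FALSE
  )
}

# Cross-chemical / cross-visit correlation matrix. With R the J x J
# same-visit block and D = diag(sqrt(icc)), the two-visit matrix is
# [R, DRD; DRD, R]: same-visit correlations equal R exactly and the two
# visits of chemical j correlate at exactly icc_j.
.simCrossCovariance <- function(config) {
  J <- sum(config@groups)
  gidx <- rep(seq_along(config@groups), times = config@groups)
  R <- matrix(config@rhoBetween, J, J)
  for (g in seq_along(config@groups)) {
    sel <- gidx == g
    R[sel, sel] <- config@rhoWithin
  }
  cgp <- config@crossGroupPairs
  if (!is.null(cgp) && nrow(cgp)) {
    gname <- names(config@groups)
    for (k in seq_len(nrow(cgp))) {
      i1 <- gidx == match(cgp$g1[k], gname)
      i2 <- gidx == match(cgp$g2[k], gname)
      R[i1, i2] <- cgp$rho[k]
      R[i2, i1] <- cgp$rho[k]
    }
  }
  diag(R) <- 1
  D <- diag(sqrt(config@icc), J)
  C <- D %*% R %*% D
  diag(C) <- config@icc
  rbind(cbind(R, C), cbind(C, R))
}

#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults emulate a
#' two-visit pregnancy biomonitoring panel: 30 metabolites in 8 mixture
#' groups (9 HMWP, 3 LMWP, 2 DINCH, 2 insecticide, 4 PAH, 3 OP,
#' 4 phenol, 3 paraben), strong within-group and weak between-group
#' log-scale correlation with an elevated LMWP-HMWP cross-block,
#' analyte-specific ICCs in the 0.1-0.65 range, and right-skewed
#' log-normal concentrations with a small below-LOD fraction.
#'
#' @param nSubjects cohort size.
#' @param groups named integer vector of chemicals per group; when the
#'   default 8-group layout is used, chemicals get metabolite names,
#'   otherwise \code{"<group>.<k>"}.
#' @param rhoWithin,rhoBetween log-scale correlations within / between
#'   groups.
#' @param crossGroupPairs data.frame (g1, g2, rho) of between-group
#'   overrides; \code{NULL} for none.
#' @param icc per-chemical (recycled) within-person correlation across
#'   the two sampling windows.
#' @param lodQuantile per-chemical (recycled) fraction of the marginal
#'   distribution below the LOD.
#' @param logMedian,logGSD per-chemical log2 medians and log2-scale
#'   SDs; defaults follow the built-in panel when applicable.
#' @param seed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSubjects = 100, seed = 1)
#' cfg
#' @export
simConfig <- function(nSubjects = 500,
                      groups = NULL,
                      rhoWithin = 0.6,
                      rhoBetween = 0.15,
                      crossGroupPairs = data.frame(
                        g1 = "LMWP", g2 = "HMWP", rho = 0.45,
                        stringsAsFactors = FALSE),
                      icc = NULL,
                      lodQuantile = 0.05,
                      logMedian = NULL,
                      logGSD = NULL,
                      seed) {
  tab <- .defaultChemicalTable()
  if (is.null(groups)) {
    groups <- table(factor(tab$group, levels = unique(tab$group)))
    groups <- setNames(as.integer(groups), names(groups))
    chemicals <- tab$chemical
    if (is.null(icc)) icc <- tab$icc
    if (is.null(logMedian)) logMedian <- tab$logMedian
    if (is.null(logGSD)) logGSD <- tab$logGSD
  } else {
    groups <- setNames(as.integer(groups), names(groups))
    chemicals <- unlist(lapply(names(groups), function(g)
      paste(g, seq_len(groups[[g]]), sep = ".")), use.names = FALSE)
  }
  J <- sum(groups)
  if (is.null(icc)) icc <- 0.4
  if (is.null(logMedian)) logMedian <- 1
  if (is.null(logGSD)) logGSD <- 1.4
  if (!is.null(crossGroupPairs) && nrow(crossGroupPairs) &&
      !all(c(crossGroupPairs$g1, crossGroupPairs$g2) %in% names(groups)))
    crossGroupPairs <- NULL
  new("SimConfig",
      nSubjects = as.integer(nSubjects),
      groups = groups,
      chemicals = chemicals,
      rhoWithin = rhoWithin,
      rhoBetween = rhoBetween,
      crossGroupPairs = crossGroupPairs,
      icc = rep_len(icc, J),
      lodQuantile = rep_len(lodQuantile, J),
      logMedian = rep_len(logMedian, J),
      logGSD = rep_len(logGSD, J),
      seed = .asSeed(seed))
}

#' Construct a ground-truth parameter record
#'
#' Builds a validated \linkS4class{SimTruth} aligned with a
#' \linkS4class{SimConfig}. Unspecified group effects default to 0 and
#' unspecified weights to equal weights within each group.
#'
#' @param config the \linkS4class{SimConfig} the truth refers to.
#' @param alpha intercept.
#' @param beta named numeric of per-group effects per quartile increase;
#'   groups not named get 0.
#' @param weights named list of per-group simplex vectors; groups not
#'   named get equal weights.
#' @param gamma named covariate coefficients (names must match columns
#'   of the expanded covariate design, e.g. \code{"age"},
#'   \code{"smokingyes"}); may be empty.
#' @param sigma residual SD.
#' @param aPath,bPath,direct mediation path coefficients.
#' @return a \linkS4class{SimTruth}.
#' @examples
#' cfg <- simConfig(nSubjects = 50, seed = 1)
#' truth <- simTruth(cfg, beta = c(LMWP = -0.12, OP = 0.14))
#' @export
simTruth <- function(config, alpha = 0, beta = numeric(0), weights = list(),
                     gamma = numeric(0), sigma = 0.5,
                     aPath = 0, bPath = 0, direct = 0) {
  stopifnot(is(config, "SimConfig"))
  gname <- names(config@groups)
  fullBeta <- setNames(numeric(length(gname)), gname)
  if (length(beta)) {
    if (!all(names(beta) %in% gname))
      stop("beta names must be mixture groups", call. = FALSE)
    fullBeta[names(beta)] <- beta
  }
  fullW <- setNames(vector("list", length(gname)), gname)
  gidx <- rep(gname, times = config@groups)
  for (g in gname) {
    J <- config@groups[[g]]
    w <- if (g %in% names(weights)) weights[[g]] else rep(1 / J, J)
    if (length(w) != J)
      stop("weights for group '", g, "' must have length ", J, call. = FALSE)
    names(w) <- config@chemicals[gidx == g]
    fullW[[g]] <- w
  }
  new("SimTruth", alpha = alpha, beta = fullBeta, weights = fullW,
      gamma = gamma, sigma = sigma,
      aPath = aPath, bPath = bPath, direct = direct)
}

#' Generate a two-visit exposure panel
#'
#' Draws log-normal urinary concentrations for every (subject,
#' chemical, visit) cell. On the log2 scale, same-visit cross-chemical
#' correlations follow the configured block structure exactly, and the
#' two visits of chemical j correlate at exactly its ICC. Values below
#' the chemical's LOD (placed at the configured quantile of its
#' marginal) are flagged non-detected and stored as missing; the
#' processing module decides fill-in values.
#'
#' @param config a valid \linkS4class{SimConfig}.
#' @return an \linkS4class{ExposureExperiment} with assays \code{t18},
#'   \code{t34} (and their \code{.detected} flags).
#' @examples
#' panel <- generateExposures(simConfig(nSubjects = 20, seed = 7))
#' panel
#' @export
generateExposures <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  J <- sum(config@groups)
  n <- config@nSubjects
  Sig <- .simCrossCovariance(config)
  eg <- eigen(Sig, symmetric = TRUE)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2 * J)
  set.seed(.deriveSeed(config@seed, "exposures"))
  Zm <- matrix(rnorm(n * 2 * J), n, 2 * J) %*% t(A)
  mu <- config@logMedian
  s <- config@logGSD
  log1 <- sweep(sweep(Zm[, seq_len(J), drop = FALSE], 2, s, "*"), 2, mu, "+")
  log2c <- sweep(sweep(Zm[, J + seq_len(J), drop = FALSE], 2, s, "*"), 2, mu, "+")
  lodQ <- pmax(config@lodQuantile, 1e-12)
  lod <- 2^(mu + s * qnorm(lodQ))
  subjects <- sprintf("S%04d", seq_len(n))
  mk <- function(lg) {
    conc <- t(2^lg)  # chemicals x subjects
    det <- conc >= lod  # lod recycles down columns (chemicals in rows)
    conc[!det] <- NA_real_
    dimnames(conc) <- dimnames(det) <- list(config@chemicals, subjects)
    list(conc = conc, det = det)
  }
  v1 <- mk(log1); v2 <- mk(log2c)
  ExposureExperiment(
    conc = list(t18 = v1$conc, t34 = v2$conc),
    detected = list(t18 = v1$det, t34 = v2$det),
    lod = setNames(lod, config@chemicals),
    groups = setNames(rep(names(config@groups), times = config@groups),
                      config@chemicals))
}

#' Generate maternal and newborn covariates
#'
#' Complete (no missingness) covariates patterned on a European urban
#' pregnancy cohort: maternal age and BMI as continuous variables;
#' parity, smoking, education, ethnicity, recruitment hospital and
#' fetal sex as categoricals. Fetal sex is balanced.
#'
#' @param nSubjects number of rows.
#' @param seed integer seed.
#' @return a data.frame with rownames \code{S0001...}.
#' @examples
#' head(generateCovariates(10, seed = 1))
#' @export
generateCovariates <- function(nSubjects, seed) {
  stopifnot(nSubjects >= 1)
  set.seed(.deriveSeed(.asSeed(seed), "covariates"))
  n <- as.integer(nSubjects)
  age <- pmin(pmax(rnorm(n, 34.3, 4.4), 18), 45)
  bmi <- exp(rnorm(n, log(23.5), 0.15))
  parity <- factor(sample(c("0", "1", "2+"), n, TRUE,
                          prob = c(0.597, 0.31, 0.093)),
                   levels = c("0", "1", "2+"))
  smoking <- factor(sample(c("no", "yes"), n, TRUE, prob = c(0.903, 0.097)),
                    levels = c("no", "yes"))
  education <- factor(sample(c("primary", "secondary", "university"), n, TRUE,
                             prob = c(0.06, 0.23, 0.71)),
                      levels = c("primary", "secondary", "university"))
  ethnicity <- factor(sample(c("european", "latinamerican", "other"), n, TRUE,
                             prob = c(0.763, 0.15, 0.087)),
                      levels = c("european", "latinamerican", "other"))
  hospital <- factor(sample(c("A", "B", "C"), n, TRUE),
                     levels = c("A", "B", "C"))
  sex <- factor(sample(c("female", "male"), n, TRUE),
                levels = c("female", "male"))
  out <- data.frame(age = age, bmi = bmi, parity = parity,
                    smoking = smoking, education = education,
                    ethnicity = ethnicity, hospital = hospital, sex = sex)
  rownames(out) <- sprintf("S%04d", seq_len(n))
  out
}

# Expanded covariate design (no intercept column) for the columns named
# in gamma; errors when a gamma name has no matching column.
.covariateDesign <- function(covariates, gamma) {
  if (!length(gamma)) {
    return(matrix(0, nrow(covariates), 0))
  }
  mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  miss <- setdiff(names(gamma), colnames(mm))
  if (length(miss))
    stop("gamma names not found in covariate design: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mm[, names(gamma), drop = FALSE]
}

# Per-subject weighted quartile-sum mean structure at one time point.
# Imputation of non-detects and log2 quartile ranking happen internally
# so the generated outcome mirrors what the fitted model assumes.
.wqsLinpred <- function(exposures, covariates, truth, timePoint, seed) {
  imp <- imputeBelowLOD(exposures, seed = .deriveSeed(seed, "lod-impute"))
  qs <- quantileRank(imp, timePoint = timePoint)
  grp <- chemGroups(exposures)
  idx <- sapply(names(truth@beta), function(g) {
    w <- truth@weights[[g]]
    qs@scores[, names(w), drop = FALSE] %*% w
  })
  lin <- truth@alpha + as.vector(idx %*% truth@beta)
  if (length(truth@gamma)) {
    Z <- .covariateDesign(covariates, truth@gamma)
    lin <- lin + as.vector(Z %*% truth@gamma)
  }
  list(lin = lin, index = idx, scores = qs)
}

#' Generate a cross-sectional outcome from the WQS mechanism
#'
#' Draws \code{y_i = alpha + sum_g beta_g (sum_j w_gj q_igj) + gamma .
#' z_i + N(0, sigma)}, where \code{q} are the quartile scores of the
#' log2 concentrations at one exposure time point (non-detects singly
#' imputed internally).
#'
#' @param exposures an \linkS4class{ExposureExperiment}.
#' @param covariates data.frame aligned with the panel's subjects.
#' @param truth a \linkS4class{SimTruth}.
#' @param seed integer seed.
#' @param timePoint which exposure window to use; defaults to the first.
#' @return named numeric vector of outcomes (z-score units).
#' @export
generateOutcome <- function(exposures, covariates, truth, seed,
                            timePoint = NULL) {
  stopifnot(is(truth, "SimTruth"))
  validObject(truth)
  seed <- .asSeed(seed)
  tp <- .checkTimePoint(exposures, timePoint)
  lp <- .wqsLinpred(exposures, covariates, truth, tp, seed)
  set.seed(.deriveSeed(seed, "outcome-noise"))
  y <- lp$lin + rnorm(length(lp$lin), 0, truth@sigma)
  setNames(y, colnames(exposures))
}

#' Generate repeated outcomes sharing a subject random intercept
#'
#' Stacks \code{nVisits} visit-level outcomes per subject: the same
#' weighted quartile-sum mean structure plus a visit fixed effect and a
#' subject-level random intercept with SD \code{subjectSD}.
#'
#' @inheritParams generateOutcome
#' @param nVisits number of visits (>= 2).
#' @param visitEffects numeric vector of visit fixed effects (length
#'   \code{nVisits}; first is the reference and is usually 0).
#' @param subjectSD SD of the shared subject-level intercept.
#' @return data.frame with columns \code{subject}, \code{visit}
#'   (factor), \code{y}.
#' @export
generateRepeatedOutcomes <- function(exposures, covariates, truth,
                                     nVisits, visitEffects = NULL,
                                     subjectSD = 0.5, seed,
                                     timePoint = NULL) {
  stopifnot(nVisits >= 2)
  seed <- .asSeed(seed)
  if (is.null(visitEffects)) visitEffects <- numeric(nVisits)
  stopifnot(length(visitEffects) == nVisits)
  tp <- .checkTimePoint(exposures, timePoint)
  lp <- .wqsLinpred(exposures, covariates, truth, tp, seed)
  n <- length(lp$lin)
  set.seed(.deriveSeed(seed, "repeated-noise"))
  u <- rnorm(n, 0, subjectSD)
  out <- do.call(rbind, lapply(seq_len(nVisits), function(v) {
    data.frame(subject = colnames(exposures),
               visit = sprintf("v%d", v),
               y = lp$lin + visitEffects[v] + u +
                 rnorm(n, 0, truth@sigma),
               stringsAsFactors = FALSE)
  }))
  out$visit <- factor(out$visit)
  rownames(out) <- NULL
  out
}

#' Generate an exposure-mediator-outcome triplet
#'
#' Draws a standard-normal exposure index, a mediator
#' \code{a * index + noise}, and an outcome \code{direct * index +
#' b * mediator + noise}, using the path coefficients stored in the
#' truth record.
#'
#' @param n sample size (>= 10).
#' @param truth a \linkS4class{SimTruth} (uses aPath, bPath, direct).
#' @param seed integer seed.
#' @param mediatorSD,outcomeSD noise SDs (0 gives the deterministic
#'   chain).
#' @return data.frame with columns \code{index}, \code{mediator},
#'   \code{outcome}.
#' @export
generateMediationTriplet <- function(n, truth, seed,
                                     mediatorSD = 1, outcomeSD = 1) {
  stopifnot(n >= 10)
  set.seed(.deriveSeed(.asSeed(seed), "mediation"))
  index <- rnorm(n)
  mediator <- truth@aPath * index + rnorm(n, 0, mediatorSD)
  outcome <- truth@direct * index + truth@bPath * mediator +
    rnorm(n, 0, outcomeSD)
  data.frame(index = index, mediator = mediator, outcome = outcome)
}

#' Tabulate a toy gestational-age reference chart
#'
#' Produces a smooth, strictly increasing median curve and a positive
#' SD curve on a weekly (or finer) GA grid — a synthetic stand-in for
#' published growth or Doppler reference charts. The default power-law
#' median roughly tracks estimated fetal weight in grams.
#'
#' @param gaRange length-2 GA range in weeks, inside (10, 43).
#' @param by grid spacing in weeks.
#' @param medianFun,sdFun functions of GA returning the median and SD;
#'   defaults \code{0.3 * ga^2.5} and 11 percent of the median.
#' @return a \linkS4class{ReferenceChart}.
#' @examples
#' makeReferenceChart(c(20, 40))
#' @export
makeReferenceChart <- function(gaRange = c(20, 40), by = 1,
                               medianFun = NULL, sdFun = NULL) {
  stopifnot(length(gaRange) == 2, gaRange[1] > 10, gaRange[2] < 43,
            gaRange[1] < gaRange[2])
  if (is.null(medianFun)) medianFun <- function(ga) 0.3 * ga^2.5
  if (is.null(sdFun)) sdFun <- function(ga) 0.11 * medianFun(ga)
  ga <- seq(gaRange[1], gaRange[2], by = by)
  new("ReferenceChart", ga = ga, median = medianFun(ga), sd = sdFun(ga))
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper producing everything the analysis pipeline
#' consumes: the two-visit exposure panel with covariates in
#' \code{colData}, a gestational age at birth, the standardized outcome
#' \code{y} generated from the WQS mechanism plus its raw (chart-scale)
#' counterpart, 32-week serum sFlt-1 and PlGF with a GA trend, and an
#' exposure-mediator-outcome pair driven by the first mixture group's
#' true index.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth a \linkS4class{SimTruth}.
#' @param chart \linkS4class{ReferenceChart} used to map the generated
#'   z-score onto a raw measurement scale.
#' @return list with elements \code{exposures} (the panel, colData
#'   holding covariates and outcome columns), \code{truth},
#'   \code{config}, \code{chart}.
#' @export
simulateCohort <- function(config, truth = simTruth(config),
                           chart = makeReferenceChart(c(28, 42.5))) {
  exposures <- generateExposures(config)
  covariates <- generateCovariates(config@nSubjects, seed = config@seed)
  y <- generateOutcome(exposures, covariates, truth, seed = config@seed)
  n <- config@nSubjects
  set.seed(.deriveSeed(config@seed, "cohort-extras"))
  gaBirth <- pmin(pmax(rnorm(n, 39.8, 1.25), min(chart@ga) + 0.2),
                  max(chart@ga) - 0.2)
  rawY <- .chartInterp(chart, gaBirth)$median +
    .chartInterp(chart, gaBirth)$sd * y
  gaSerum <- runif(n, 31, 33)
  plgf <- exp(rnorm(n, log(350), 0.5))
  lp <- .wqsLinpred(exposures, covariates, truth, timePoints(exposures)[1],
                    seed = config@seed)
  idx1 <- as.numeric(scale(lp$index[, 1]))
  log2ratio <- 2 + 0.35 * (gaSerum - 32) + 0.4 * rnorm(n)
  sflt <- plgf * 2^log2ratio
  mediator <- truth@aPath * idx1 + rnorm(n)
  medOutcome <- truth@direct * idx1 + truth@bPath * mediator + rnorm(n)
  cd <- SummarizedExperiment::colData(exposures)
  for (v in names(covariates)) cd[[v]] <- covariates[[v]]
  cd$gaBirth <- gaBirth
  cd$y <- as.numeric(y)
  cd$rawY <- rawY
  cd$gaSerum <- gaSerum
  cd$sflt <- sflt
  cd$plgf <- plgf
  cd$mediator <- mediator
  cd$medOutcome <- medOutcome
  SummarizedExperiment::colData(exposures) <- cd
  list(exposures = exposures, truth = truth, config = config, chart = chart)
}
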