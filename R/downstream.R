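#' Weighted mixture index
#'
#' Per-subject index \code{s_i = sum_j w_j x_ij}: each chemical's log2
#' concentration multiplied by its (estimated) weight and summed over
#' the group's chemicals. This is the continuous exposure summary used
#' for effect-modification and mediation analyses.
#'
#' @param weights named simplex vector over the group's chemicals
#'   (e.g. one element of [mixtureWeights()]).
#' @param x an \linkS4class{ExposureExperiment} with no missing cells
#'   at the requested time point (log2-transformed internally when
#'   still on the concentration scale), or a numeric matrix of log2
#'   values (subjects x chemicals).
#' @param timePoint exposure window (panel input only).
#' @return named numeric vector of indices with the weights attached as
#'   attribute \code{"weights"}.
#' @export
mixtureIndex <- function(weights, x, timePoint = NULL) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  if (is(x, "ExposureExperiment")) {
    tp <- .checkTimePoint(x, timePoint)
    conc <- SummarizedExperiment::assay(x, tp)
    if (any(is.na(conc)))
      stop("panel has missing cells; impute below-LOD values first",
           call. = FALSE)
    lg <- if (isTRUE(S4Vectors::metadata(x)$logScale)) conc else log2(conc)
    lg <- t(lg)
  } else {
    lg <- as.matrix(x)
  }
  miss <- setdiff(names(weights), colnames(lg))
  if (length(miss))
    stop("weights name chemicals absent from the panel: ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- as.vector(lg[, names(weights), drop = FALSE] %*% weights)
  names(s) <- rownames(lg)
  attr(s, "weights") <- weights
  s
}

#' Fetal-sex effect modification of a mixture index
#'
#' Fits one adjusted linear model with a multiplicative
#' index-by-sex interaction term; the p-value for effect modification
#' is the Wald p of the product coefficient. Sex-specific slopes come
#' from stratified adjusted fits.
#'
#' @param index continuous mixture index.
#' @param sex factor with two levels (first level is the reference).
#' @param outcome continuous outcome.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list with \code{slopes} (named per sex level),
#'   \code{pInteraction}, \code{interaction} (the product-term
#'   estimate) and \code{n}.
#' @export
sexInteractionTest <- function(index, sex, outcome, covariates = NULL) {
  sex <- droplevels(factor(sex))
  if (nlevels(sex) != 2L)
    stop("both sexes must be represented", call. = FALSE)
  if (any(table(sex) < 10L))
    stop("need at least 10 subjects per sex", call. = FALSE)
  df <- data.frame(.y = outcome, .x = index, .sex = sex)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- lm(.y ~ . + .x:.sex, data = df)
  sm <- summary(fit)$coefficients
  iaRow <- grep(":", rownames(sm), fixed = TRUE)
  if (length(iaRow) != 1L) stop("interaction term not found")
  slopes <- vapply(levels(sex), function(lv) {
    sub <- df[df$.sex == lv, setdiff(names(df), ".sex"), drop = FALSE]
    coef(lm(.y ~ ., data = sub))[[".x"]]
  }, numeric(1))
  list(slopes = slopes,
       interaction = unname(sm[iaRow, "Estimate"]),
       pInteraction = unname(sm[iaRow, "Pr(>|t|)"]),
       n = nrow(df))
}

#' Single-pollutant association
#'
#' Adjusted ordinary least squares of the outcome on one chemical's
#' exposure, with a normal-theory 95 percent confidence interval.
#'
#' @param x single exposure (e.g. log2 concentration or quartile
#'   score).
#' @param outcome continuous outcome.
#' @param covariates optional data.frame of adjustment covariates.
#' @return named numeric: beta, ciLow, ciHigh, se, p, n.
#' @export
singlePollutantAssoc <- function(x, outcome, covariates = NULL) {
  df <- data.frame(.y = outcome, .x = x)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design; aliased columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)$coefficients
  est <- sm[".x", "Estimate"]; se <- sm[".x", "Std. Error"]
  tq <- qt(0.975, df.residual(fit))
  c(beta = est, ciLow = est - tq * se, ciHigh = est + tq * se,
    se = se, p = sm[".x", "Pr(>|t|)"], n = nrow(df))
}

#' @importFrom stats df.residual lm.fit
NULL

# Product-of-coefficients decomposition on one data set.
# Columns of Xm/Xy are fixed; rows are resampled by the bootstrap.
.mediateOnce <- function(Xm, Xy, mediatorCol, indexCol, m, y) {
  fm <- lm.fit(Xm, m)
  fy <- lm.fit(Xy, y)
  a <- fm$coefficients[indexCol]
  b <- fy$coefficients[mediatorCol]
  ade <- fy$coefficients[indexCol]
  c(a = unname(a), b = unname(b), acme = unname(a * b),
    ade = unname(ade), total = unname(a * b + ade))
}

#' Causal mediation by product of coefficients with bootstrap inference
#'
#' Decomposes the exposure-outcome association into the average causal
#' mediation effect (ACME, the product of the exposure-to-mediator and
#' adjusted mediator-to-outcome coefficients), the average direct
#' effect (ADE) and the total effect (their sum, which in this linear
#' no-interaction model equals the OLS total-effect coefficient
#' exactly). Inference is by nonparametric bootstrap: subjects are
#' resampled with replacement, both models are refitted per replicate,
#' and percentile confidence intervals plus a two-sided bootstrap
#' p-value for the ACME are reported.
#'
#' @param index continuous exposure (mixture index).
#' @param mediator continuous mediator.
#' @param outcome continuous outcome.
#' @param covariates optional data.frame of adjustment covariates
#'   (entered in both models).
#' @param nBoot number of bootstrap resamples (>= 100; the analysis
#'   convention is 10,000).
#' @param seed integer seed for the resampling.
#' @return a \linkS4class{MediationResult}.
#' @examples
#' truth <- simTruth(simConfig(nSubjects = 10, seed = 1),
#'                   aPath = 0.5, bPath = 0.4, direct = -0.1)
#' tri <- generateMediationTriplet(500, truth, seed = 1)
#' mediate(tri$index, tri$mediator, tri$outcome, nBoot = 200, seed = 1)
#' @export
mediate <- function(index, mediator, outcome, covariates = NULL,
                    nBoot = 10000, seed) {
  stopifnot(nBoot >= 100)
  seed <- .asSeed(seed)
  ok <- is.finite(index) & is.finite(mediator) & is.finite(outcome)
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
    C <- model.matrix(~ ., data = covariates[ok, , drop = FALSE])[, -1, drop = FALSE]
  }
  index <- index[ok]; mediator <- mediator[ok]; outcome <- outcome[ok]
  n <- length(index)
  if (var(mediator) == 0) stop("mediator is constant", call. = FALSE)
  Xm <- cbind(`(Intercept)` = 1, index = index, C)
  Xy <- cbind(`(Intercept)` = 1, mediator = mediator, index = index, C)
  est <- .mediateOnce(Xm, Xy, "mediator", "index", mediator, outcome)
  if (anyNA(est))
    stop("mediator and exposure are collinear (or the design is rank ",
         "deficient); the product-of-coefficients decomposition is not ",
         "identified", call. = FALSE)

  set.seed(.deriveSeed(seed, "mediate-boot"))
  boot <- matrix(NA_real_, nBoot, 6,
                 dimnames = list(NULL, c("a", "b", "acme", "ade", "total",
                                         "prop")))
  for (r in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    e <- .mediateOnce(Xm[idx, , drop = FALSE], Xy[idx, , drop = FALSE],
                      "mediator", "index", mediator[idx], outcome[idx])
    if (anyNA(e)) next  # degenerate resample; left out of the percentiles
    boot[r, 1:5] <- e
    boot[r, 6] <- if (abs(e["total"]) > 1e-10) e["acme"] / e["total"] else NA
  }
  prop <- if (abs(est["total"]) > 1e-10) est["acme"] / est["total"] else {
    warning("total effect indistinguishable from 0; proportion mediated undefined",
            call. = FALSE)
    NA_real_
  }
  ci <- t(apply(boot[, c("acme", "ade", "total", "prop"), drop = FALSE], 2,
                quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  rownames(ci) <- c("acme", "ade", "total", "propMediated")
  colnames(ci) <- c("lower", "upper")
  pv <- 2 * min(mean(boot[, "acme"] <= 0, na.rm = TRUE),
                mean(boot[, "acme"] >= 0, na.rm = TRUE))
  new("MediationResult",
      estimates = c(aPath = unname(est["a"]), bPath = unname(est["b"]),
                    acme = unname(est["acme"]), ade = unname(est["ade"]),
                    total = unname(est["total"]),
                    propMediated = unname(prop)),
      ci = ci, pValue = min(pv, 1), nBoot = as.integer(nBoot),
      seed = seed, n = as.integer(n))
}
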