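#' @import methods
#' @importFrom stats qnorm rnorm runif rbinom quantile sd var median
#'   lm coef vcov model.matrix complete.cases optim pnorm qt resid
#'   setNames rcauchy predict cor
#' @importFrom utils head read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib mixBWQS, .registration = TRUE
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Simulation configuration for a synthetic pregnancy cohort
#'
#' Describes the exposure-generating mechanism of a synthetic cohort:
#' how many subjects, how chemicals are grouped into mixtures, the
#' log-scale correlation structure within and between mixture groups,
#' per-chemical reproducibility across the two urine-sampling windows
#' (ICC), and the fraction of each chemical's distribution falling
#' below its limit of detection (LOD).
#'
#' The implied 2J x 2J cross-chemical, cross-visit correlation matrix
#' (J chemicals at two time points) must be positive definite; this is
#' checked at construction.
#'
#' @slot nSubjects number of pregnant participants.
#' @slot groups named integer vector: chemicals per mixture group.
#' @slot chemicals character vector of chemical (metabolite) names,
#'   ordered by group.
#' @slot rhoWithin log-scale correlation between chemicals of the same
#'   group, in [0, 1).
#' @slot rhoBetween log-scale correlation between chemicals of
#'   different groups, in [0, 1).
#' @slot crossGroupPairs data.frame (g1, g2, rho) overriding
#'   \code{rhoBetween} for specific group pairs (e.g. the elevated
#'   LMWP-HMWP cross-correlation seen in biomonitoring panels).
#' @slot icc per-chemical within-person correlation of log
#'   concentrations across the two sampling windows, in [0, 1].
#' @slot lodQuantile per-chemical fraction of the marginal
#'   distribution below the LOD, in [0, 1).
#' @slot logMedian per-chemical log2 median concentration (ng/mL).
#' @slot logGSD per-chemical log2-scale geometric SD.
#' @slot seed integer seed governing all randomness of the generator.
#'
#' @seealso [simConfig()] for the user-facing constructor with
#'   cohort-realistic defaults.
#' @export
setClass("SimConfig",
  representation(
    nSubjects = "integer",
    groups = "integer",
    chemicals = "character",
    rhoWithin = "numeric",
    rhoBetween = "numeric",
    crossGroupPairs = "data.frameOrNULL",
    icc = "numeric",
    lodQuantile = "numeric",
    logMedian = "numeric",
    logGSD = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  J <- sum(object@groups)
  msg <- character(0)
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (is.null(names(object@groups)) || anyDuplicated(names(object@groups)))
    msg <- c(msg, "groups must be uniquely named")
  if (length(object@chemicals) != J || anyDuplicated(object@chemicals))
    msg <- c(msg, "chemicals must be unique and match sum(groups)")
  if (object@rhoWithin < 0 || object@rhoWithin >= 1)
    msg <- c(msg, "rhoWithin must be in [0, 1)")
  if (object@rhoBetween < 0 || object@rhoBetween >= 1)
    msg <- c(msg, "rhoBetween must be in [0, 1)")
  if (length(object@icc) != J || any(object@icc < 0) || any(object@icc > 1))
    msg <- c(msg, "icc must have one value in [0, 1] per chemical")
  if (length(object@lodQuantile) != J ||
      any(object@lodQuantile < 0) || any(object@lodQuantile >= 1))
    msg <- c(msg, "lodQuantile must have one value in [0, 1) per chemical")
  if (length(object@logMedian) != J || length(object@logGSD) != J ||
      any(object@logGSD <= 0))
    msg <- c(msg, "logMedian/logGSD must be per-chemical with logGSD > 0")
  if (length(msg) == 0L) {
    Sig <- .simCrossCovariance(object)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    # positive semi-definite allowed (icc = 1 makes the two visits
    # perfectly dependent); genuinely indefinite matrices are rejected
    if (min(ev) < -1e-8 * max(ev))
      msg <- c(msg, "implied cross-chemical/cross-visit correlation matrix is not positive (semi-)definite")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Records the generating parameters of a synthetic cohort: the mean
#' structure of the weighted-quantile-sum outcome model (intercept,
#' per-group effects per quartile increase, simplex weights, covariate
#' coefficients, residual SD) and the exposure-mediator-outcome path
#' coefficients used for mediation data. Downstream recovery tests
#' consume the cohort together with this object, never re-derived
#' values.
#'
#' @slot alpha intercept (outcome z-score units).
#' @slot beta named numeric, one effect per mixture group per quartile
#'   increase.
#' @slot weights named list of per-group simplex weight vectors; each
#'   is nonnegative and sums to 1.
#' @slot gamma named numeric of covariate coefficients (names match
#'   design-matrix columns; may be empty).
#' @slot sigma residual SD, > 0.
#' @slot aPath exposure-to-mediator slope.
#' @slot bPath mediator-to-outcome slope.
#' @slot direct exposure-to-outcome direct slope.
#' @export
setClass("SimTruth",
  representation(
    alpha = "numeric", beta = "numeric", weights = "list",
    gamma = "numeric", sigma = "numeric",
    aPath = "numeric", bPath = "numeric", direct = "numeric"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character(0)
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(object@beta) != length(object@weights) ||
      !identical(names(object@beta), names(object@weights)))
    msg <- c(msg, "beta and weights must be aligned by group name")
  for (g in names(object@weights)) {
    w <- object@weights[[g]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
      msg <- c(msg, sprintf("weights for group '%s' must be nonnegative and sum to 1", g))
  }
  if (length(msg)) msg else TRUE
})

#' Gestational-age reference chart
#'
#' A tabulated reference chart giving the population median and SD of
#' an outcome (e.g. estimated fetal weight, a Doppler pulsatility
#' index) on a grid of gestational ages. Z-scores are obtained by
#' linear interpolation between grid points; no extrapolation outside
#' the grid is permitted.
#'
#' @slot ga gestational ages in weeks, strictly increasing.
#' @slot median outcome median at each grid GA.
#' @slot sd outcome SD at each grid GA, all > 0.
#' @export
setClass("ReferenceChart",
  representation(ga = "numeric", median = "numeric", sd = "numeric")
)

setValidity("ReferenceChart", function(object) {
  msg <- character(0)
  n <- length(object@ga)
  if (n < 2L) msg <- c(msg, "chart needs at least two grid points")
  if (any(diff(object@ga) <= 0)) msg <- c(msg, "ga grid must be strictly increasing")
  if (length(object@median) != n || length(object@sd) != n)
    msg <- c(msg, "median and sd must match the ga grid")
  if (any(object@sd <= 0)) msg <- c(msg, "all sd entries must be > 0")
  if (length(msg)) msg else TRUE
})

#' Subject x chemical x visit exposure container
#'
#' A \linkS4class{SummarizedExperiment} holding urinary biomarker
#' concentrations (ng/mL). Rows are chemicals, columns are subjects.
#' For each sampling time point \code{tp} there is a numeric
#' concentration assay named \code{tp} (NA where no instrument signal
#' was detected) and a logical assay named \code{paste0(tp,
#' ".detected")}. \code{rowData} carries the per-chemical limit of
#' detection (\code{lod}, > 0) and mixture \code{group}; \code{colData}
#' carries subject covariates (and any outcome columns).
#'
#' @seealso [ExposureExperiment()] constructor; accessors
#'   [timePoints()], [concMatrix()], [detectedMatrix()], [chemLOD()],
#'   [chemGroups()].
#' @export
setClass("ExposureExperiment", contains = "SummarizedExperiment")

setValidity("ExposureExperiment", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  tps <- an[!grepl("\\.detected$", an)]
  if (length(tps) == 0L) msg <- c(msg, "no concentration assays")
  for (tp in tps) {
    if (!paste0(tp, ".detected") %in% an)
      msg <- c(msg, sprintf("missing detection-flag assay for time point '%s'", tp))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("lod", "group") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'lod' and 'group'")
  } else if (any(!is.finite(rd$lod)) || any(rd$lod <= 0)) {
    msg <- c(msg, "every chemical must have a finite lod > 0")
  }
  # positivity applies on the concentration scale only; a log2-scale
  # container (metadata logScale = TRUE) legitimately holds negatives
  if (!isTRUE(S4Vectors::metadata(object)$logScale)) {
    for (tp in tps) {
      if (!paste0(tp, ".detected") %in% an) next
      conc <- SummarizedExperiment::assay(object, tp)
      det <- SummarizedExperiment::assay(object, paste0(tp, ".detected"))
      bad <- det & (is.na(conc) | conc <= 0)
      if (any(bad))
        msg <- c(msg, sprintf("time point '%s': detected cells must hold a positive value", tp))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Quartile scores of one exposure time point
#'
#' Integer scores in {0, 1, 2, 3} assigned to each (subject, chemical)
#' cell by ranking the chemical's log2 concentrations against its own
#' empirical 25/50/75 percentiles (the stored cutpoints). Ties promote
#' to the upper bin. These scores are the design input of the
#' weighted quantile sum model; effects are interpreted per quartile
#' increase.
#'
#' @slot scores integer matrix, subjects in rows, chemicals in columns.
#' @slot cutpoints 3 x J matrix of per-chemical 25/50/75 percentiles of
#'   the log2 concentrations.
#' @slot timePoint label of the exposure assessment window.
#' @export
setClass("QuantScores",
  representation(scores = "matrix", cutpoints = "matrix", timePoint = "character")
)

setValidity("QuantScores", function(object) {
  msg <- character(0)
  s <- object@scores
  if (any(is.na(s)) || any(!s %in% 0:3))
    msg <- c(msg, "scores must be integers in {0, 1, 2, 3} with no missing cells")
  if (ncol(object@cutpoints) != ncol(s) || nrow(object@cutpoints) != 3L)
    msg <- c(msg, "cutpoints must be a 3 x ncol(scores) matrix")
  if (length(msg)) msg else TRUE
})

#' Aligned design of a multigroup BWQS model
#'
#' Internal bookkeeping product of [buildDesign()]: outcome, quartile
#' scores with chemicals ordered contiguously by group, expanded
#' covariate contrasts, and (for the repeated-outcome variant) the
#' subject index of each row.
#'
#' @slot y numeric outcome vector (one row per subject, or per
#'   subject-visit in the repeated-outcome case).
#' @slot Q numeric matrix of quartile scores, columns grouped.
#' @slot Z numeric covariate design (0 columns if unadjusted).
#' @slot groups factor of length ncol(Q) mapping chemical columns to
#'   mixture groups, levels in column order.
#' @slot subject integer subject index per row (length 0 when
#'   cross-sectional).
#' @slot nSubjects number of distinct subjects.
#' @slot nDropped rows removed as incomplete.
#' @slot outcomeName label for reporting.
#' @export
setClass("LbwqsrDesign",
  representation(
    y = "numeric", Q = "matrix", Z = "matrix", groups = "factor",
    subject = "integer", nSubjects = "integer", nDropped = "integer",
    outcomeName = "character"
  )
)

setValidity("LbwqsrDesign", function(object) {
  msg <- character(0)
  n <- length(object@y)
  if (nrow(object@Q) != n) msg <- c(msg, "Q rows must match y")
  if (nrow(object@Z) != n) msg <- c(msg, "Z rows must match y")
  if (length(object@groups) != ncol(object@Q))
    msg <- c(msg, "groups must map every column of Q")
  if (is.unsorted(as.integer(object@groups)))
    msg <- c(msg, "columns of Q must be contiguous by group")
  if (length(object@subject) && length(object@subject) != n)
    msg <- c(msg, "subject index must match rows")
  if (length(msg)) msg else TRUE
})

#' Posterior of a fitted multigroup BWQS model
#'
#' Holds the retained posterior draws (iterations x chains x
#' parameters) of a penalized multigroup Bayesian Weighted Quantile Sum
#' fit, along with split R-hat and effective-sample-size diagnostics,
#' divergence counts, and the design it was fitted to.
#'
#' Parameters include the intercept \code{alpha}, one group coefficient
#' \code{beta[g]} per mixture (the joint effect of a one-quartile
#' increase in all its chemicals, weighted), the simplex weights
#' \code{w[chemical]}, covariate coefficients \code{gamma[.]}, the
#' residual SD \code{sigma}, the shared shrinkage scale \code{tau}
#' (elastic-net prior only) and, in the repeated-outcome variant, the
#' subject random-intercept SD \code{sigma_u}.
#'
#' @slot draws 3-d array of posterior draws with dimnames
#'   (iteration, chain, parameter).
#' @slot groups factor mapping chemical columns to mixture groups.
#' @slot diagnostics data.frame with per-parameter split R-hat and ESS.
#' @slot divergences integer count of divergent transitions per chain.
#' @slot converged logical; FALSE when any split R-hat >= 1.05 or total
#'   ESS < 100 per chain.
#' @slot prior list of prior settings (type, lambda, dirichletAlpha, ...).
#' @slot sampler list of sampler settings (chains, warmup, draws, seed,
#'   target acceptance).
#' @slot design the \linkS4class{LbwqsrDesign} fitted.
#' @export
setClass("LbwqsrFit",
  representation(
    draws = "array", groups = "factor", diagnostics = "data.frame",
    divergences = "integer", converged = "logical",
    prior = "list", sampler = "list", design = "LbwqsrDesign"
  )
)

setValidity("LbwqsrFit", function(object) {
  msg <- character(0)
  if (length(dim(object@draws)) != 3L)
    msg <- c(msg, "draws must be iterations x chains x parameters")
  if (is.null(dimnames(object@draws)[[3]]))
    msg <- c(msg, "parameter dimension must be named")
  if (length(msg)) msg else TRUE
})

#' Bootstrap causal-mediation result
#'
#' Product-of-coefficients mediation decomposition with nonparametric
#' bootstrap inference: the a-path (exposure to mediator), the b-path
#' (mediator to outcome, exposure-adjusted), the average causal
#' mediation effect ACME = a*b, the average direct effect, the total
#' effect (= ACME + direct in the linear no-interaction model), the
#' proportion mediated, percentile bootstrap confidence intervals and a
#' two-sided bootstrap p-value for the ACME.
#'
#' @slot estimates named numeric: aPath, bPath, acme, ade, total,
#'   propMediated (NA when the total effect is indistinguishable from 0).
#' @slot ci matrix of percentile bootstrap intervals (rows acme, ade,
#'   total, propMediated; columns lower, upper).
#' @slot pValue two-sided bootstrap p-value for the ACME.
#' @slot nBoot number of bootstrap resamples.
#' @slot seed RNG seed used for resampling.
#' @slot n analysis sample size.
#' @export
setClass("MediationResult",
  representation(
    estimates = "numeric", ci = "matrix", pValue = "numeric",
    nBoot = "integer", seed = "integer", n = "integer"
  )
)

setValidity("MediationResult", function(object) {
  need <- c("aPath", "bPath", "acme", "ade", "total", "propMediated")
  msg <- character(0)
  if (!all(need %in% names(object@estimates)))
    msg <- c(msg, "estimates must contain aPath, bPath, acme, ade, total, propMediated")
  e <- object@estimates
  if (all(c("acme", "ade", "total") %in% names(e)) &&
      abs(e[["acme"]] + e[["ade"]] - e[["total"]]) > 1e-8)
    msg <- c(msg, "acme + ade must equal total")
  if (any(object@ci[, 1] > object@ci[, 2], na.rm = TRUE))
    msg <- c(msg, "CI bounds must be ordered")
  if (length(msg)) msg else TRUE
})
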