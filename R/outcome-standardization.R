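# Linear interpolation of a reference chart at arbitrary GAs.
.chartInterp <- function(chart, ga) {
  if (any(ga < min(chart@ga) - 1e-9) || any(ga > max(chart@ga) + 1e-9))
    stop("gestational age outside the chart grid; extrapolation is not supported",
         call. = FALSE)
  list(median = approx(chart@ga, chart@median, xout = ga, rule = 1)$y,
       sd = approx(chart@ga, chart@sd, xout = ga, rule = 1)$y)
}

#' Gestational-age z-score from a reference chart
#'
#' Standardizes a raw measurement against a tabulated reference chart:
#' the chart's median and SD are linearly interpolated between the two
#' adjacent grid gestational ages and \code{z = (value - median(ga)) /
#' sd(ga)}. GAs outside the chart grid raise an error — reference
#' charts must not be extrapolated.
#'
#' @param value raw measurement(s).
#' @param ga gestational age(s) in weeks, inside the chart grid.
#' @param chart a \linkS4class{ReferenceChart}.
#' @return numeric z-score(s).
#' @examples
#' ch <- makeReferenceChart(c(20, 40))
#' zscoreFromChart(0.3 * 30^2.5, 30, ch)  # on the median: 0
#' @export
zscoreFromChart <- function(value, ga, chart) {
  stopifnot(is(chart, "ReferenceChart"))
  ref <- .chartInterp(chart, ga)
  (value - ref$median) / ref$sd
}

#' @importFrom stats approx
NULL

# Median (tau = 0.5) regression of log(value) on a polynomial in GA,
# solved by Nelder-Mead minimisation of the absolute-deviation loss
# from the OLS start. Two- or three-parameter fits converge reliably.
.medianRegression <- function(logv, ga, degree = 1) {
  X <- cbind(1, stats::poly(ga, degree, raw = TRUE))
  start <- qr.solve(X, logv)
  loss <- function(b) sum(abs(logv - X %*% b))
  fit <- optim(start, loss, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  # polish: a second restart guards against premature simplex collapse
  fit <- optim(fit$par, loss, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  list(coef = fit$par, fitted = as.vector(X %*% fit$par), degree = degree)
}

#' Multiples of the median by gestational age
#'
#' Standardizes a positive biomarker by GA: a median (tau = 0.5)
#' quantile regression of \code{log(value)} on GA is fitted in the
#' sample and each observation is divided by its fitted GA-specific
#' median, \code{mom_i = value_i / exp(fitted_i)}. By construction
#' about half the sample lies below MoM = 1.
#'
#' @param values positive biomarker values.
#' @param ga gestational ages (weeks) with some spread.
#' @param degree polynomial degree of the GA term (default linear on
#'   the log scale).
#' @return list with elements \code{mom} (positive, median about 1),
#'   \code{coef} (fitted log-median curve) and \code{degree}.
#' @export
momStandardize <- function(values, ga, degree = 1) {
  if (length(values) < 20L)
    stop("need at least 20 observations for a stable median fit",
         call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("MoM standardization requires positive values", call. = FALSE)
  if (length(unique(ga)) < 2L)
    stop("degenerate gestational ages: no GA spread", call. = FALSE)
  fit <- .medianRegression(log(values), ga, degree = degree)
  list(mom = values / exp(fit$fitted), coef = fit$coef, degree = degree)
}

#' Log2 ratio of two positive biomarkers
#'
#' \code{log2(sflt / plgf)}: the antiangiogenic-to-proangiogenic
#' balance on a symmetric scale (swapping the arguments flips the
#' sign).
#'
#' @param sflt,plgf positive concentrations (pg/mL).
#' @return numeric log2 ratio(s).
#' @examples
#' log2Ratio(8, 2)   # 2
#' log2Ratio(15, 10) # log2(1.5)
#' @export
log2Ratio <- function(sflt, plgf) {
  if (any(!is.finite(sflt)) || any(sflt <= 0) ||
      any(!is.finite(plgf)) || any(plgf <= 0))
    stop("both biomarkers must be positive", call. = FALSE)
  log2(sflt / plgf)
}

#' GA-standardized sFlt-1/PlGF ratio
#'
#' Combines [log2Ratio()] and [momStandardize()]. The default order
#' follows the reporting convention of computing the ratio, log2
#' transforming it, and then standardizing by GA; the alternative
#' computes MoM of the raw ratio first and then log2 transforms, which
#' is well defined even when the log2 ratio takes nonpositive values.
#'
#' @param sflt,plgf positive serum concentrations.
#' @param ga gestational ages at blood draw.
#' @param order \code{"log2-then-mom"} (default; requires all log2
#'   ratios > 0) or \code{"mom-then-log2"}.
#' @param degree polynomial degree passed to [momStandardize()].
#' @return numeric standardized values.
#' @export
ratioStandardize <- function(sflt, plgf, ga,
                             order = c("log2-then-mom", "mom-then-log2"),
                             degree = 1) {
  order <- match.arg(order)
  r <- log2Ratio(sflt, plgf)
  if (order == "log2-then-mom") {
    if (any(r <= 0))
      stop("log2 ratio has nonpositive values; use order = 'mom-then-log2'",
           call. = FALSE)
    momStandardize(r, ga, degree = degree)$mom
  } else {
    log2(momStandardize(sflt / plgf, ga, degree = degree)$mom)
  }
}
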