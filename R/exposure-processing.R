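#' Single imputation of below-LOD concentrations
#'
#' Fills every non-detected cell with exactly one value strictly inside
#' (0, LOD). The default draws from a log-normal fitted to the
#' chemical's detected values at that time point, truncated to
#' (0, LOD) — standard biomonitoring practice that preserves the shape
#' of the left tail. A deterministic \code{"lod/sqrt2"} fill-in is
#' available for sensitivity analyses. Detected cells are untouched.
#'
#' @param x an \linkS4class{ExposureExperiment} on the concentration
#'   scale.
#' @param seed integer seed (used by the truncated-log-normal method).
#' @param method \code{"truncated-lognormal"} (default) or
#'   \code{"lod/sqrt2"}.
#' @return the panel with all cells populated; detection flags are
#'   preserved so imputed cells remain identifiable.
#' @details With fewer than 3 detected values for a chemical the
#'   log-normal fit is undefined and that chemical falls back to
#'   LOD/sqrt(2).
#' @export
imputeBelowLOD <- function(x, seed,
                           method = c("truncated-lognormal", "lod/sqrt2")) {
  stopifnot(is(x, "ExposureExperiment"))
  method <- match.arg(method)
  lod <- chemLOD(x)
  if (any(!is.finite(lod)) || any(lod <= 0))
    stop("every chemical needs a finite LOD > 0", call. = FALSE)
  if (isTRUE(S4Vectors::metadata(x)$logScale))
    stop("impute before log transformation", call. = FALSE)
  set.seed(.deriveSeed(.asSeed(seed), "below-lod"))
  for (tp in timePoints(x)) {
    conc <- SummarizedExperiment::assay(x, tp)
    det <- SummarizedExperiment::assay(x, paste0(tp, ".detected"))
    for (j in seq_len(nrow(conc))) {
      nd <- which(!det[j, ])
      if (!length(nd)) next
      obs <- conc[j, det[j, ]]
      obs <- obs[is.finite(obs) & obs > 0]
      if (method == "truncated-lognormal" && length(obs) >= 3) {
        m <- mean(log(obs)); s <- sd(log(obs))
        if (s > 0) {
          pcap <- pnorm((log(lod[j]) - m) / s)
          # inverse-CDF draw from the log-normal left tail below LOD
          u <- runif(length(nd)) * pcap
          v <- exp(m + s * qnorm(pmax(u, .Machine$double.xmin)))
          conc[j, nd] <- pmin(pmax(v, .Machine$double.xmin),
                              lod[j] * (1 - 1e-12))
          next
        }
      }
      conc[j, nd] <- lod[j] / sqrt(2)
    }
    SummarizedExperiment::assay(x, tp) <- conc
  }
  x
}

#' Log2-transform a concentration panel
#'
#' Elementwise log base 2 of every concentration assay. All cells must
#' be present and positive (run [imputeBelowLOD()] first); the first
#' offending cell is named in the error.
#'
#' @param x an \linkS4class{ExposureExperiment} on the concentration
#'   scale.
#' @return the panel on the log2 scale (flagged in its metadata).
#' @export
log2Transform <- function(x) {
  stopifnot(is(x, "ExposureExperiment"))
  if (isTRUE(S4Vectors::metadata(x)$logScale))
    stop("panel is already on the log2 scale", call. = FALSE)
  for (tp in timePoints(x)) {
    conc <- SummarizedExperiment::assay(x, tp)
    bad <- which(is.na(conc) | conc <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("nonpositive or missing concentration at chemical '%s', subject '%s', time point '%s'",
                   rownames(conc)[bad[1, 1]], colnames(conc)[bad[1, 2]], tp),
           call. = FALSE)
    SummarizedExperiment::assay(x, tp) <- log2(conc)
  }
  S4Vectors::metadata(x)$logScale <- TRUE
  x
}

#' Quartile scores
#'
#' Ranks each chemical's log2 concentrations against its own empirical
#' 25/50/75 percentiles (linear-interpolation quantiles): the score is
#' the number of cutpoints less than or equal to the value, so ties
#' promote to the upper bin and scores lie in {0, 1, 2, 3}. Because
#' ranking is invariant to strictly monotone transforms, scoring raw or
#' log2 values gives identical results; the log2 step matters only for
#' the stored cutpoints.
#'
#' @param x a numeric vector (one chemical across subjects) or an
#'   \linkS4class{ExposureExperiment} with no missing cells at the
#'   requested time point.
#' @param timePoint exposure window (panel method only).
#' @param ... unused.
#' @return for a vector, an integer vector with the cutpoints as an
#'   attribute; for a panel, a \linkS4class{QuantScores} (subjects x
#'   chemicals).
#' @examples
#' quantileRank(c(1, 2, 3, 4))
#' @export
setGeneric("quantileRank", function(x, ...) standardGeneric("quantileRank"))

#' @describeIn quantileRank score one chemical's values.
#' @export
setMethod("quantileRank", "numeric", function(x, ...) {
  if (length(x) < 4L || any(is.na(x)))
    stop("need at least 4 complete observations to form quartiles",
         call. = FALSE)
  cuts <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- vapply(x, function(v) sum(cuts <= v), integer(1))
  attr(s, "cutpoints") <- cuts
  s
})

#' @describeIn quantileRank score every chemical of one time point;
#'   raw concentrations are log2-transformed internally.
#' @export
setMethod("quantileRank", "ExposureExperiment", function(x, timePoint = NULL, ...) {
  tp <- .checkTimePoint(x, timePoint)
  conc <- SummarizedExperiment::assay(x, tp)
  if (any(is.na(conc)))
    stop("panel has missing cells at time point '", tp,
         "'; impute below-LOD values first", call. = FALSE)
  lg <- if (isTRUE(S4Vectors::metadata(x)$logScale)) conc else log2(conc)
  scores <- matrix(0L, ncol(lg), nrow(lg),
                   dimnames = list(colnames(lg), rownames(lg)))
  cuts <- matrix(NA_real_, 3, nrow(lg),
                 dimnames = list(c("25%", "50%", "75%"), rownames(lg)))
  for (j in seq_len(nrow(lg))) {
    s <- quantileRank(lg[j, ])
    scores[, j] <- as.integer(s)
    cuts[, j] <- attr(s, "cutpoints")
  }
  new("QuantScores", scores = scores, cutpoints = cuts, timePoint = tp)
})

#' Pairwise Spearman correlations of one exposure window
#'
#' Rank-based correlation matrix across chemicals (average ranks for
#' ties), computed on pairwise-complete observations. A zero-variance
#' chemical yields NA entries (undefined, never 0).
#'
#' @param x an \linkS4class{ExposureExperiment}.
#' @param timePoint exposure window; defaults to the first.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(x, timePoint = NULL) {
  tp <- .checkTimePoint(x, timePoint)
  conc <- SummarizedExperiment::assay(x, tp)
  if (ncol(conc) < 3L)
    stop("need at least 3 subjects", call. = FALSE)
  suppressWarnings(
    cor(t(conc), method = "spearman", use = "pairwise.complete.obs"))
}

#' Intraclass correlation between the two sampling windows
#'
#' One-way random-effects ICC for two occasions, computed on log2
#' concentrations of subjects with both time points:
#' \code{(MSB - MSW) / (MSB + MSW)}, with MSB/MSW the between- and
#' within-subject ANOVA mean squares. Negative estimates are reported
#' as computed unless \code{floorZero = TRUE}.
#'
#' @param x an \linkS4class{ExposureExperiment} with two (or more; the
#'   first two are used) time points.
#' @param chemicals subset of chemicals; defaults to all.
#' @param floorZero truncate negative ICCs at 0.
#' @return data.frame with columns chemical, icc, msb, msw, n (complete
#'   pairs).
#' @export
iccRepeatability <- function(x, chemicals = NULL, floorZero = FALSE) {
  tps <- timePoints(x)
  if (length(tps) < 2L) stop("need two exposure time points", call. = FALSE)
  c1 <- SummarizedExperiment::assay(x, tps[1])
  c2 <- SummarizedExperiment::assay(x, tps[2])
  if (!isTRUE(S4Vectors::metadata(x)$logScale)) {
    c1 <- log2(c1); c2 <- log2(c2)
  }
  if (is.null(chemicals)) chemicals <- rownames(x)
  out <- lapply(chemicals, function(ch) {
    x1 <- c1[ch, ]; x2 <- c2[ch, ]
    ok <- is.finite(x1) & is.finite(x2)
    n <- sum(ok)
    if (n < 3L)
      stop("chemical '", ch, "' has fewer than 3 complete pairs",
           call. = FALSE)
    x1 <- x1[ok]; x2 <- x2[ok]
    m <- (x1 + x2) / 2
    gm <- mean(m)
    msb <- 2 * sum((m - gm)^2) / (n - 1)
    msw <- sum((x1 - x2)^2 / 2) / n
    icc <- (msb - msw) / (msb + msw)
    if (floorZero) icc <- max(icc, 0)
    data.frame(chemical = ch, icc = icc, msb = msb, msw = msw, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
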