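#' @describeIn timePoints concentration-assay labels, in storage order.
#' @export
setMethod("timePoints", "ExposureExperiment", function(x) {
  an <- SummarizedExperiment::assayNames(x)
  an[!grepl("\\.detected$", an)]
})

.checkTimePoint <- function(x, timePoint) {
  tps <- timePoints(x)
  if (missing(timePoint) || is.null(timePoint)) return(tps[1L])
  if (!timePoint %in% tps)
    stop("unknown time point '", timePoint, "'; available: ",
         paste(tps, collapse = ", "), call. = FALSE)
  timePoint
}

#' @describeIn concMatrix extract one time point's concentrations.
#' @export
setMethod("concMatrix", "ExposureExperiment", function(x, timePoint) {
  tp <- .checkTimePoint(x, timePoint)
  SummarizedExperiment::assay(x, tp)
})

#' @describeIn detectedMatrix extract one time point's detection flags.
#' @export
setMethod("detectedMatrix", "ExposureExperiment", function(x, timePoint) {
  tp <- .checkTimePoint(x, timePoint)
  SummarizedExperiment::assay(x, paste0(tp, ".detected"))
})

#' @describeIn chemLOD LODs from \code{rowData}.
#' @export
setMethod("chemLOD", "ExposureExperiment", function(x) {
  setNames(SummarizedExperiment::rowData(x)$lod, rownames(x))
})

#' @describeIn chemGroups group map from \code{rowData}.
#' @export
setMethod("chemGroups", "ExposureExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  setNames(factor(rd$group, levels = unique(rd$group)), rownames(x))
})

#' @describeIn posteriorDraws pooled draws across chains.
#' @export
setMethod("posteriorDraws", "LbwqsrFit", function(object, parameter) {
  pn <- dimnames(object@draws)[[3]]
  if (!parameter %in% pn)
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  as.vector(object@draws[, , parameter])
})

setMethod("show", "ExposureExperiment", function(object) {
  cat(sprintf("ExposureExperiment: %d chemicals x %d subjects, %d time point(s): %s\n",
              nrow(object), ncol(object), length(timePoints(object)),
              paste(timePoints(object), collapse = ", ")))
  grp <- chemGroups(object)
  cat(sprintf("mixture groups: %s\n",
              paste(sprintf("%s(%d)", levels(grp), table(grp)), collapse = ", ")))
  for (tp in timePoints(object)) {
    det <- detectedMatrix(object, tp)
    cat(sprintf("  %s: %.1f%% detected\n", tp, 100 * mean(det)))
  }
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d subjects, %d chemicals in %d groups (seed %d)\n",
              object@nSubjects, sum(object@groups), length(object@groups),
              object@seed))
  cat(sprintf("  rho within %.2f / between %.2f; ICC range [%.2f, %.2f]; LOD quantile range [%.2f, %.2f]\n",
              object@rhoWithin, object@rhoBetween,
              min(object@icc), max(object@icc),
              min(object@lodQuantile), max(object@lodQuantile)))
  invisible(object)
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: per-quartile group effects\n")
  print(round(object@beta, 3))
  cat(sprintf("  alpha %.3f, sigma %.3f; mediation a=%.2f b=%.2f direct=%.2f\n",
              object@alpha, object@sigma, object@aPath, object@bPath,
              object@direct))
  invisible(object)
})

setMethod("show", "ReferenceChart", function(object) {
  cat(sprintf("ReferenceChart: GA %.1f-%.1f weeks (%d grid points), median %.1f-%.1f\n",
              min(object@ga), max(object@ga), length(object@ga),
              min(object@median), max(object@median)))
  invisible(object)
})

setMethod("show", "QuantScores", function(object) {
  cat(sprintf("QuantScores ('%s'): %d subjects x %d chemicals; score table:\n",
              object@timePoint, nrow(object@scores), ncol(object@scores)))
  print(table(factor(object@scores, levels = 0:3)))
  invisible(object)
})

setMethod("show", "LbwqsrFit", function(object) {
  d <- dim(object@draws)
  cat(sprintf("LbwqsrFit: %d draws x %d chains, %d parameters (prior: %s)\n",
              d[1], d[2], d[3], object@prior$type))
  cat(sprintf("  n = %d, %d mixture groups, %d chemicals\n",
              length(object@design@y), nlevels(object@groups),
              length(object@groups)))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f, divergences %d; converged: %s\n",
              max(object@diagnostics$rhat, na.rm = TRUE),
              min(object@diagnostics$ess, na.rm = TRUE),
              sum(object@divergences), object@converged))
  print(summarizePosterior(object), digits = 3)
  invisible(object)
})

setMethod("show", "MediationResult", function(object) {
  e <- object@estimates
  cat(sprintf("MediationResult (n = %d, %d bootstrap resamples)\n",
              object@n, object@nBoot))
  cat(sprintf("  a-path %.4f, b-path %.4f\n", e["aPath"], e["bPath"]))
  cat(sprintf("  ACME  %.4f [%.4f, %.4f], p = %.4g\n",
              e["acme"], object@ci["acme", 1], object@ci["acme", 2],
              object@pValue))
  cat(sprintf("  ADE   %.4f [%.4f, %.4f]\n",
              e["ade"], object@ci["ade", 1], object@ci["ade", 2]))
  cat(sprintf("  total %.4f [%.4f, %.4f]\n",
              e["total"], object@ci["total", 1], object@ci["total", 2]))
  if (is.finite(e["propMediated"]))
    cat(sprintf("  proportion mediated %.3f [%.3f, %.3f]\n",
                e["propMediated"], object@ci["propMediated", 1],
                object@ci["propMediated", 2]))
  else cat("  proportion mediated: undefined (total effect ~ 0)\n")
  invisible(object)
})
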