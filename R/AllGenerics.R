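#' Time points of an exposure container
#'
#' @param x an \linkS4class{ExposureExperiment}.
#' @return character vector of time-point labels.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' Concentration matrix at one time point
#'
#' @param x an \linkS4class{ExposureExperiment}.
#' @param timePoint time-point label; defaults to the first.
#' @return numeric matrix (chemicals x subjects), NA where non-detected.
#' @export
setGeneric("concMatrix", function(x, timePoint) standardGeneric("concMatrix"))

#' Detection flags at one time point
#'
#' @inheritParams concMatrix
#' @return logical matrix (chemicals x subjects).
#' @export
setGeneric("detectedMatrix", function(x, timePoint) standardGeneric("detectedMatrix"))

#' Per-chemical limits of detection
#'
#' @param x an \linkS4class{ExposureExperiment}.
#' @return named numeric vector of LODs (ng/mL).
#' @export
setGeneric("chemLOD", function(x) standardGeneric("chemLOD"))

#' Chemical-to-mixture-group map
#'
#' @param x an \linkS4class{ExposureExperiment}.
#' @return named factor mapping each chemical to its mixture group.
#' @export
setGeneric("chemGroups", function(x) standardGeneric("chemGroups"))

#' Summarize a fitted multigroup BWQS posterior
#'
#' @param object a fitted model.
#' @param ... further arguments.
#' @return a data.frame; see the method documentation.
#' @export
setGeneric("summarizePosterior", function(object, ...) standardGeneric("summarizePosterior"))

#' Posterior-mean mixture weights
#'
#' @param object a fitted model.
#' @return named list of per-group weight vectors, each summing to 1.
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' Posterior draws of a parameter
#'
#' @param object a fitted model.
#' @param parameter parameter name (e.g. \code{"beta[LMWP]"}).
#' @return numeric vector pooling all chains.
#' @export
setGeneric("posteriorDraws", function(object, parameter) standardGeneric("posteriorDraws"))
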