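#' Build an exposure container
#'
#' Assembles concentration matrices, detection flags, per-chemical LODs
#' and the chemical-to-mixture-group map into a validated
#' \linkS4class{ExposureExperiment}.
#'
#' @param conc named list of numeric matrices (chemicals x subjects),
#'   one per time point; cells without instrument signal must be NA.
#' @param detected named list of logical matrices parallel to
#'   \code{conc}; when omitted, a cell is considered detected iff its
#'   concentration is present.
#' @param lod named numeric vector of limits of detection (ng/mL),
#'   one per chemical, all > 0.
#' @param groups named character/factor mapping each chemical to its
#'   mixture group.
#' @param colData optional data.frame of subject covariates.
#' @return an \linkS4class{ExposureExperiment}.
#' @examples
#' conc <- matrix(c(1.2, NA, 3.1, 0.8), 2, 2,
#'                dimnames = list(c("MEP", "BPA"), c("S1", "S2")))
#' ExposureExperiment(list(t18 = conc), lod = c(MEP = 0.1, BPA = 0.9),
#'                    groups = c(MEP = "LMWP", BPA = "PHENOL"))
#' @export
ExposureExperiment <- function(conc, detected = NULL, lod, groups,
                               colData = NULL) {
  stopifnot(is.list(conc), length(conc) >= 1, !is.null(names(conc)))
  chems <- rownames(conc[[1]])
  if (is.null(chems)) stop("concentration matrices need chemical rownames")
  if (is.null(detected))
    detected <- lapply(conc, function(m) !is.na(m))
  assays <- list()
  for (tp in names(conc)) {
    assays[[tp]] <- conc[[tp]]
    assays[[paste0(tp, ".detected")]] <- detected[[tp]]
  }
  rd <- S4Vectors::DataFrame(
    lod = as.numeric(lod[chems]),
    group = as.character(groups[chems]),
    row.names = chems)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = if (is.null(colData)) {
      S4Vectors::DataFrame(row.names = colnames(conc[[1]]))
    } else S4Vectors::DataFrame(colData))
  new("ExposureExperiment", se)
}
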