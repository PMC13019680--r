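#' Write an exposure panel to long-format CSV
#'
#' One row per (subject, chemical, time point): columns
#' \code{subject_id, chemical, time_point, value, lod, detected}.
#' Non-detected cells have empty \code{value}.
#'
#' @param x an \linkS4class{ExposureExperiment}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExposureCSV <- function(x, path) {
  rows <- lapply(timePoints(x), function(tp) {
    conc <- SummarizedExperiment::assay(x, tp)
    det <- SummarizedExperiment::assay(x, paste0(tp, ".detected"))
    data.frame(
      subject_id = rep(colnames(conc), each = nrow(conc)),
      chemical = rep(rownames(conc), times = ncol(conc)),
      time_point = tp,
      value = as.vector(conc),
      lod = rep(chemLOD(x), times = ncol(conc)),
      detected = as.vector(det),
      stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  grp <- chemGroups(x)
  long$group <- as.character(grp[long$chemical])
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read an exposure panel from long-format CSV
#'
#' Inverse of [writeExposureCSV()].
#'
#' @param path CSV written by [writeExposureCSV()] (columns
#'   \code{subject_id, chemical, time_point, value, lod, detected,
#'   group}).
#' @return an \linkS4class{ExposureExperiment}.
#' @export
readExposureCSV <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "chemical", "time_point", "value", "lod",
            "detected", "group")
  if (!all(need %in% names(long)))
    stop("exposure CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  chems <- unique(long$chemical)
  subjects <- unique(long$subject_id)
  tps <- unique(long$time_point)
  conc <- list(); det <- list()
  for (tp in tps) {
    sub <- long[long$time_point == tp, ]
    m <- matrix(NA_real_, length(chems), length(subjects),
                dimnames = list(chems, subjects))
    d <- matrix(FALSE, length(chems), length(subjects),
                dimnames = list(chems, subjects))
    m[cbind(sub$chemical, sub$subject_id)] <- sub$value
    d[cbind(sub$chemical, sub$subject_id)] <- as.logical(sub$detected)
    conc[[tp]] <- m; det[[tp]] <- d
  }
  first <- long[!duplicated(long$chemical), ]
  ExposureExperiment(conc, det,
                     lod = setNames(first$lod, first$chemical),
                     groups = setNames(first$group, first$chemical))
}

#' Write a reference chart as CSV
#'
#' @param chart a \linkS4class{ReferenceChart}.
#' @param path output file (columns \code{ga_week, median, sd}).
#' @return the path, invisibly.
#' @export
writeChartCSV <- function(chart, path) {
  write.csv(data.frame(ga_week = chart@ga, median = chart@median,
                       sd = chart@sd),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a reference chart from CSV
#'
#' @param path CSV with columns \code{ga_week, median, sd}.
#' @return a \linkS4class{ReferenceChart}.
#' @export
readChartCSV <- function(path) {
  d <- read.csv(path)
  new("ReferenceChart", ga = d$ga_week, median = d$median, sd = d$sd)
}

#' Write a posterior summary table as CSV
#'
#' Mirrors the reporting layout of mixture-effect tables: one row per
#' (group, outcome) with the posterior mean effect per quartile
#' increase, the central 95 percent credible interval, and the
#' significance flag.
#'
#' @param results data.frame from [summarizePosterior()] (columns
#'   group, outcome, n, beta, cri_low, cri_high, significant).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data.frame", call. = FALSE)
  need <- c("group", "outcome", "n", "beta", "cri_low", "cri_high",
            "significant")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(results$cri_low > results$cri_high))
    stop("credible-interval bounds are out of order", call. = FALSE)
  write.csv(results[, need], path, row.names = FALSE)
  invisible(path)
}
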