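.pipelineDefaults <- function() {
  list(
    input = "synthetic",
    outdir = NULL,
    seed = NULL,
    nSubjects = 300,
    beta = list(LMWP = -0.25),
    sigma = 0.5,
    aPath = 0.5, bPath = 0.4, direct = -0.1,
    prior = "elastic-net", lambda = 0.5, dirichletAlpha = 1,
    timePoint = "t18",
    chains = 2, warmup = 500, iter = 500, targetAccept = 0.9,
    analyses = list(mediation = TRUE, sexInteraction = TRUE,
                    singlePollutant = TRUE, timeVarying = FALSE)
  )
}

.pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.pipelineDefaults(), config)
  if (is.null(cfg$seed) || !.isCount(cfg$seed))
    stop("a master seed is mandatory", call. = FALSE)
  if (is.null(cfg$outdir)) stop("an output directory is required", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  # fail fast before any stage runs
  if (!identical(cfg$input, "synthetic")) {
    need <- c("exposures", "covariates", "outcomes")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss))
      stop("input must name files: ", paste(miss, collapse = ", "),
           call. = FALSE)
    for (f in unlist(cfg$input[need]))
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    oc <- names(read.csv(cfg$input$outcomes, nrows = 1))
    if (isTRUE(cfg$analyses$mediation) &&
        !all(c("mediator", "medOutcome") %in% oc))
      stop("mediation is enabled but the outcome table has no mediator columns",
           call. = FALSE)
  }
  cfg
}

.plog <- function(logfile, ...) {
  line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  paste0(...))
  cat(line, "\n", file = logfile, append = TRUE)
  message(line)
}

#' Run the full mixture analysis pipeline
#'
#' Orchestrates simulate (or load) - process - standardize - fit -
#' downstream from a single configuration, writing every stage's
#' outputs as CSV under the configured output directory. All
#' randomness derives deterministically from the mandatory master
#' seed, so re-running an identical configuration reproduces every
#' result file bit-identically.
#'
#' Stage outputs: \code{exposures.csv}, \code{covariates.csv},
#' \code{outcomes.csv}, \code{chart.csv}, \code{truth.json}
#' (simulate); \code{icc.csv}, \code{spearman.csv}, \code{qscores.csv}
#' (process); \code{outcomes_std.csv} (standardize);
#' \code{results.csv}, \code{weights.csv} (fit); \code{mediation.csv},
#' \code{interaction.csv}, \code{single_pollutant.csv} (downstream).
#'
#' @param config a list or a YAML file path. Mandatory fields:
#'   \code{seed}, \code{outdir}. Optional: \code{input}
#'   (\code{"synthetic"} or named file paths), cohort settings
#'   (\code{nSubjects}, \code{beta}, \code{sigma}, path coefficients),
#'   model settings (\code{prior}, \code{lambda},
#'   \code{dirichletAlpha}, \code{timePoint}), sampler settings
#'   (\code{chains}, \code{warmup}, \code{iter},
#'   \code{targetAccept}) and analysis toggles (\code{analyses$...}).
#' @return invisibly, a list with the fitted model, the summary table
#'   and the paths of all written files.
#' @export
runPipeline <- function(config) {
  cfg <- .pipelineConfig(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, "pipeline.log")
  cat("", file = logfile)
  paths <- list()
  p <- function(f) file.path(cfg$outdir, f)

  ## stage 1: simulate or load ------------------------------------------
  if (identical(cfg$input, "synthetic")) {
    .plog(logfile, "simulate: generating synthetic cohort, n = ",
          cfg$nSubjects)
    simSeed <- .deriveSeed(cfg$seed, "stage-simulate")
    scfg <- simConfig(nSubjects = cfg$nSubjects, seed = simSeed)
    truth <- simTruth(scfg, beta = unlist(cfg$beta), sigma = cfg$sigma,
                      gamma = c(age = 0.02, smokingyes = -0.15),
                      aPath = cfg$aPath, bPath = cfg$bPath,
                      direct = cfg$direct)
    chart <- makeReferenceChart(c(28, 42.5))
    cohort <- simulateCohort(scfg, truth, chart)
    cd <- as.data.frame(SummarizedExperiment::colData(cohort$exposures))
    writeExposureCSV(cohort$exposures, paths$exposures <- p("exposures.csv"))
    covCols <- c("age", "bmi", "parity", "smoking", "education",
                 "ethnicity", "hospital", "sex")
    write.csv(cbind(subject_id = rownames(cd), cd[covCols]),
              paths$covariates <- p("covariates.csv"), row.names = FALSE)
    outCols <- c("gaBirth", "rawY", "gaSerum", "sflt", "plgf",
                 "mediator", "medOutcome")
    write.csv(cbind(subject_id = rownames(cd), cd[outCols]),
              paths$outcomes <- p("outcomes.csv"), row.names = FALSE)
    writeChartCSV(chart, paths$chart <- p("chart.csv"))
    jsonlite::write_json(
      list(config = list(nSubjects = scfg@nSubjects,
                         groups = as.list(scfg@groups),
                         seed = scfg@seed),
           truth = list(alpha = truth@alpha, beta = as.list(truth@beta),
                        weights = lapply(truth@weights, as.list),
                        sigma = truth@sigma, aPath = truth@aPath,
                        bPath = truth@bPath, direct = truth@direct)),
      paths$truth <- p("truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    .plog(logfile, "load: reading cohort files")
    file.copy(cfg$input$exposures, paths$exposures <- p("exposures.csv"),
              overwrite = TRUE)
    file.copy(cfg$input$covariates, paths$covariates <- p("covariates.csv"),
              overwrite = TRUE)
    file.copy(cfg$input$outcomes, paths$outcomes <- p("outcomes.csv"),
              overwrite = TRUE)
    if (!is.null(cfg$input$chart))
      file.copy(cfg$input$chart, paths$chart <- p("chart.csv"),
                overwrite = TRUE)
  }

  ## stage 2: process exposures -----------------------------------------
  .plog(logfile, "process: LOD imputation, quartile scores, Spearman, ICC")
  panel <- readExposureCSV(paths$exposures)
  procSeed <- .deriveSeed(cfg$seed, "stage-process")
  panelImp <- imputeBelowLOD(panel, seed = procSeed)
  qs <- quantileRank(panelImp, timePoint = cfg$timePoint)
  write.csv(cbind(subject_id = rownames(qs@scores),
                  as.data.frame(qs@scores, check.names = FALSE)),
            paths$qscores <- p("qscores.csv"), row.names = FALSE)
  sp <- spearmanMatrix(panelImp, timePoint = cfg$timePoint)
  write.csv(cbind(chemical = rownames(sp),
                  as.data.frame(sp, check.names = FALSE)),
            paths$spearman <- p("spearman.csv"), row.names = FALSE)
  icc <- iccRepeatability(panelImp)
  write.csv(icc, paths$icc <- p("icc.csv"), row.names = FALSE)

  ## stage 3: standardize outcomes --------------------------------------
  .plog(logfile, "standardize: chart z-scores and ratio MoM")
  outcomes <- read.csv(paths$outcomes, stringsAsFactors = FALSE)
  chart <- readChartCSV(paths$chart)
  std <- data.frame(subject_id = outcomes$subject_id,
                    y_z = zscoreFromChart(outcomes$rawY, outcomes$gaBirth,
                                          chart))
  std$ratio_mom <- ratioStandardize(outcomes$sflt, outcomes$plgf,
                                    outcomes$gaSerum)
  write.csv(std, paths$outcomesStd <- p("outcomes_std.csv"),
            row.names = FALSE)

  ## stage 4: fit the multigroup model ----------------------------------
  .plog(logfile, "fit: multigroup BWQS (", cfg$chains, " chains x ",
        cfg$iter, " draws)")
  covariates <- read.csv(paths$covariates, stringsAsFactors = TRUE,
                         row.names = 1)
  stopifnot(identical(rownames(qs@scores), rownames(covariates)))
  design <- buildDesign(qs, chemGroups(panel), covariates,
                        outcome = std$y_z, outcomeName = "y_z")
  fit <- fitLbwqsr(design, prior = cfg$prior, lambda = cfg$lambda,
                   dirichletAlpha = cfg$dirichletAlpha,
                   chains = cfg$chains, warmup = cfg$warmup,
                   iter = cfg$iter, targetAccept = cfg$targetAccept,
                   seed = .deriveSeed(cfg$seed, "stage-fit"))
  summary <- summarizePosterior(fit)
  writeResultsTable(summary, paths$results <- p("results.csv"))
  wt <- attr(summary, "weights")
  wdf <- do.call(rbind, lapply(names(wt), function(g)
    data.frame(group = g, chemical = names(wt[[g]]),
               weight = unname(wt[[g]]), stringsAsFactors = FALSE)))
  write.csv(wdf, paths$weights <- p("weights.csv"), row.names = FALSE)
  .plog(logfile, "fit: max split R-hat = ",
        round(max(fit@diagnostics$rhat, na.rm = TRUE), 3),
        ", min ESS = ", round(min(fit@diagnostics$ess, na.rm = TRUE)),
        ", divergences = ", sum(fit@divergences))

  ## stage 5: downstream inference --------------------------------------
  dsSeed <- .deriveSeed(cfg$seed, "stage-downstream")
  g1 <- levels(design@groups)[1]
  idx <- mixtureIndex(mixtureWeights(fit)[[g1]],
                      log2Transform(panelImp), timePoint = cfg$timePoint)
  if (isTRUE(cfg$analyses$sexInteraction)) {
    .plog(logfile, "downstream: fetal-sex effect modification")
    it <- sexInteractionTest(idx, covariates$sex, std$y_z,
                             covariates[setdiff(names(covariates), "sex")])
    write.csv(data.frame(group = g1,
                         beta_female = it$slopes[["female"]],
                         beta_male = it$slopes[["male"]],
                         p_interaction = it$pInteraction, n = it$n),
              paths$interaction <- p("interaction.csv"), row.names = FALSE)
  }
  if (isTRUE(cfg$analyses$mediation)) {
    .plog(logfile, "downstream: bootstrap mediation")
    med <- mediate(idx, outcomes$mediator, outcomes$medOutcome,
                   nBoot = 2000, seed = dsSeed)
    e <- med@estimates
    write.csv(data.frame(group = g1,
                         a_path = e["aPath"], b_path = e["bPath"],
                         acme = e["acme"], ade = e["ade"],
                         total = e["total"],
                         prop_mediated = e["propMediated"],
                         ci_low = med@ci["acme", 1],
                         ci_high = med@ci["acme", 2],
                         p = med@pValue, n = med@n, n_boot = med@nBoot,
                         seed = med@seed),
              paths$mediation <- p("mediation.csv"), row.names = FALSE)
  }
  if (isTRUE(cfg$analyses$singlePollutant)) {
    .plog(logfile, "downstream: single-pollutant regressions")
    lg <- concMatrix(log2Transform(panelImp), cfg$timePoint)
    sp1 <- do.call(rbind, lapply(rownames(lg), function(ch) {
      a <- singlePollutantAssoc(lg[ch, ], std$y_z, covariates)
      data.frame(chemical = ch, beta = a["beta"], ci_low = a["ciLow"],
                 ci_high = a["ciHigh"], p = a["p"], n = a["n"],
                 stringsAsFactors = FALSE)
    }))
    write.csv(sp1, paths$singlePollutant <- p("single_pollutant.csv"),
              row.names = FALSE)
  }
  if (isTRUE(cfg$analyses$timeVarying) && identical(cfg$input, "synthetic")) {
    .plog(logfile, "downstream: time-varying repeated-outcome model")
    rep <- generateRepeatedOutcomes(cohort$exposures,
                                    covariates[covCols], truth,
                                    nVisits = 2, subjectSD = 0.5,
                                    seed = .deriveSeed(cfg$seed, "stage-tv"))
    tvFit <- fitTimeVarying(rep, qs, chemGroups(panel),
                            covariates[covCols],
                            prior = cfg$prior, chains = cfg$chains,
                            warmup = cfg$warmup, iter = cfg$iter,
                            seed = .deriveSeed(cfg$seed, "stage-tv-fit"))
    writeResultsTable(summarizePosterior(tvFit),
                      paths$resultsTimeVarying <- p("results_time_varying.csv"))
  }
  .plog(logfile, "done")
  invisible(list(fit = fit, summary = summary, paths = paths, config = cfg))
}
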