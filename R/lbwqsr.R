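#' Assemble a multigroup BWQS design
#'
#' Aligns quartile scores, the chemical-to-group map, covariates and
#' the outcome into a fitting-ready design: chemical columns are
#' reordered contiguously by mixture group, categorical covariates are
#' expanded to reference-coded indicator contrasts, and incomplete rows
#' are dropped (with a message reporting the count).
#'
#' @param quantScores a \linkS4class{QuantScores} (or plain integer
#'   matrix of scores, subjects x chemicals).
#' @param groups named character/factor mapping every chemical to its
#'   mixture group; a chemical present in the scores but absent here is
#'   an error.
#' @param covariates data.frame of adjustment covariates aligned with
#'   the score rows (NULL for an unadjusted model).
#' @param outcome numeric outcome aligned with the score rows.
#' @param subject optional subject identifier per row (repeated-outcome
#'   designs); defaults to one row per subject.
#' @param outcomeName label used in summaries.
#' @return an \linkS4class{LbwqsrDesign}.
#' @export
buildDesign <- function(quantScores, groups, covariates = NULL, outcome,
                        subject = NULL, outcomeName = "y") {
  scores <- if (is(quantScores, "QuantScores")) quantScores@scores else quantScores
  chems <- colnames(scores)
  if (is.null(chems)) stop("score columns must be named by chemical")
  miss <- setdiff(chems, names(groups))
  if (length(miss))
    stop("chemicals missing from the group map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  grp <- groups[chems]
  grp <- factor(as.character(grp), levels = unique(as.character(grp)))
  ord <- order(as.integer(grp))
  scores <- scores[, ord, drop = FALSE]
  grp <- grp[ord]
  names(grp) <- colnames(scores)

  n <- nrow(scores)
  stopifnot(length(outcome) == n)
  keep <- is.finite(outcome)
  hasCov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  if (hasCov) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    keep <- keep & complete.cases(covariates)
  }
  Z <- if (hasCov) {
    model.matrix(~ ., data = covariates[keep, , drop = FALSE])[, -1, drop = FALSE]
  } else matrix(0, sum(keep), 0)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " incomplete row(s) excluded from the design")
  subject <- if (is.null(subject)) integer(0) else {
    s <- as.integer(factor(subject[keep]))
    s
  }
  new("LbwqsrDesign",
      y = as.numeric(outcome[keep]),
      Q = matrix(as.numeric(scores[keep, , drop = FALSE]), sum(keep),
                 ncol(scores), dimnames = list(NULL, colnames(scores))),
      Z = Z,
      groups = grp,
      subject = subject,
      nSubjects = if (length(subject)) max(subject) else sum(keep),
      nDropped = as.integer(nDropped),
      outcomeName = outcomeName)
}

.defaultHyper <- function() {
  list(sd_alpha = 10, sd_gamma = 10, sigma_scale = 5, sigma_u_scale = 1)
}

# Unconstrained dimension of the sampler's parameter vector.
.paramDim <- function(G, K, V, enet, S) {
  1L + G + K + V + (if (enet) 1L else 0L) + 1L + (if (S > 0) 1L + S else 0L)
}

.paramNames <- function(design, enet, ranef) {
  c("alpha",
    paste0("beta[", levels(design@groups), "]"),
    if (ncol(design@Z)) paste0("gamma[", colnames(design@Z), "]"),
    paste0("w[", names(design@groups), "]"),
    if (enet) "tau",
    "sigma",
    if (ranef) "sigma_u",
    "lp__")
}

#' Fit the penalized multigroup Bayesian WQS model
#'
#' Samples the posterior of the multigroup weighted quantile sum model
#' with the built-in No-U-Turn sampler. The outcome mean is
#' \code{alpha + sum_g beta_g (sum_j w_gj q_igj) + z_i' gamma}; each
#' group's weights follow a Dirichlet prior on the simplex
#' (stick-breaking parameterization), and the group coefficients carry
#' an elastic-net shrinkage prior \code{p(beta | tau) proportional to
#' exp(-lambda |beta|/tau - (1 - lambda) beta^2 / (2 tau^2))} with a
#' single shared scale \code{tau ~ half-Cauchy(0, 1)} — the "shared
#' variance with a single origin" that pools shrinkage across groups.
#' Group effects are unconstrained in sign. A flat coefficient prior
#' (no shrinkage, no tau) is available for sensitivity checks and
#' degenerate-limit validation.
#'
#' After sampling, split R-hat and effective sample sizes are computed
#' for every parameter; the fit is flagged (with a warning) when any
#' split R-hat is 1.05 or more, when total ESS falls below 100 per
#' chain, or when more than 5 percent of post-warmup transitions
#' diverge.
#'
#' @param design an \linkS4class{LbwqsrDesign} from [buildDesign()].
#' @param prior \code{"elastic-net"} (default) or \code{"flat"}.
#' @param lambda elastic-net mixing in [0, 1]: 1 is pure LASSO
#'   (Laplace), 0 pure ridge (Gaussian); default 0.5.
#' @param dirichletAlpha concentration of the Dirichlet weight prior.
#' @param fixedWeights optional named list of per-group simplex vectors;
#'   when given, weights are held fixed instead of sampled.
#' @param chains,warmup,iter MCMC geometry (post-warmup \code{iter}
#'   draws per chain).
#' @param targetAccept dual-averaging acceptance target.
#' @param maxTreedepth NUTS doubling cap.
#' @param seed integer seed; chain seeds are derived deterministically.
#' @param hyper prior scales (\code{sd_alpha}, \code{sd_gamma},
#'   \code{sigma_scale}, \code{sigma_u_scale}).
#' @return an \linkS4class{LbwqsrFit}.
#' @examples
#' \donttest{
#' cfg <- simConfig(nSubjects = 150, seed = 3)
#' truth <- simTruth(cfg, beta = c(LMWP = -0.3))
#' cohort <- simulateCohort(cfg, truth)
#' qs <- quantileRank(imputeBelowLOD(cohort$exposures, seed = 3))
#' des <- buildDesign(qs, chemGroups(cohort$exposures),
#'                    outcome = cohort$exposures$y)
#' fit <- fitLbwqsr(des, chains = 2, warmup = 300, iter = 300, seed = 3)
#' summarizePosterior(fit)
#' }
#' @export
fitLbwqsr <- function(design,
                      prior = c("elastic-net", "flat"),
                      lambda = 0.5,
                      dirichletAlpha = 1,
                      fixedWeights = NULL,
                      chains = 4, warmup = 1000, iter = 1000,
                      targetAccept = 0.9, maxTreedepth = 10,
                      seed, hyper = .defaultHyper()) {
  stopifnot(is(design, "LbwqsrDesign"))
  validObject(design)
  prior <- match.arg(prior)
  stopifnot(lambda >= 0, lambda <= 1)
  seed <- .asSeed(seed)
  G <- nlevels(design@groups)
  gsize <- as.integer(table(design@groups))
  J <- ncol(design@Q)
  K <- ncol(design@Z)
  S <- if (length(design@subject)) design@nSubjects else 0L
  enet <- prior == "elastic-net"
  fixw <- !is.null(fixedWeights)
  wfix <- numeric(J)
  if (fixw) {
    for (g in levels(design@groups)) {
      w <- fixedWeights[[g]]
      sel <- design@groups == g
      if (is.null(w) || length(w) != sum(sel) ||
          any(w < 0) || abs(sum(w) - 1) > 1e-8)
        stop("fixedWeights for group '", g,
             "' must be a simplex vector of length ", sum(sel),
             call. = FALSE)
      if (!is.null(names(w))) w <- w[names(design@groups)[sel]]
      wfix[sel] <- w
    }
  }
  V <- if (fixw) 0L else J - G
  dim <- .paramDim(G, K, V, enet, S)

  drawsList <- vector("list", chains)
  div <- integer(chains)
  for (ch in seq_len(chains)) {
    chainSeed <- .deriveSeed(seed, paste0("lbwqsr-chain-", ch))
    set.seed(chainSeed)
    init <- rnorm(dim, 0, 0.1)
    init[1] <- mean(design@y) + rnorm(1, 0, 0.1)
    lsigPos <- 1L + G + K + V + (if (enet) 1L else 0L) + 1L
    init[lsigPos] <- log(max(sd(design@y), 0.1)) + rnorm(1, 0, 0.1)
    res <- .lbwqsrNuts(design@y, design@Q, design@Z, gsize,
                       if (S > 0) design@subject - 1L else integer(0), S,
                       if (enet) 0L else 1L, lambda, dirichletAlpha,
                       fixw, wfix, hyper, init,
                       as.integer(warmup), as.integer(iter),
                       targetAccept, as.integer(maxTreedepth),
                       as.numeric(chainSeed))
    drawsList[[ch]] <- res$draws
    div[ch] <- res$divergent
  }
  pn <- .paramNames(design, enet, S > 0)
  draws <- array(NA_real_, c(iter, chains, length(pn)),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)), pn))
  for (ch in seq_len(chains)) draws[, ch, ] <- drawsList[[ch]]

  diag <- .fitDiagnostics(draws)
  converged <- max(diag$rhat, na.rm = TRUE) < 1.05 &&
    min(diag$ess, na.rm = TRUE) > 100 * chains
  if (!converged)
    warning("convergence diagnostics flag this fit: max split R-hat = ",
            round(max(diag$rhat, na.rm = TRUE), 3), ", min ESS = ",
            round(min(diag$ess, na.rm = TRUE), 1), call. = FALSE)
  if (sum(div) > 0.05 * chains * iter)
    warning(sprintf("%.1f%% divergent transitions; posterior may be biased",
                    100 * sum(div) / (chains * iter)), call. = FALSE)
  new("LbwqsrFit",
      draws = draws, groups = design@groups, diagnostics = diag,
      divergences = div, converged = converged,
      prior = list(type = prior, lambda = lambda,
                   dirichletAlpha = dirichletAlpha,
                   fixedWeights = fixedWeights, hyper = hyper),
      sampler = list(chains = chains, warmup = warmup, iter = iter,
                     targetAccept = targetAccept,
                     maxTreedepth = maxTreedepth, seed = seed),
      design = design)
}

# Per-parameter split R-hat and total ESS; constant parameters
# (e.g. the weight of a single-chemical group) are skipped.
.fitDiagnostics <- function(draws) {
  pn <- dimnames(draws)[[3]]
  out <- data.frame(parameter = pn, rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_along(pn)) {
    d <- draws[, , p, drop = FALSE]
    dim(d) <- dim(draws)[1:2]
    if (all(abs(d - d[1]) < 1e-12)) next
    out$rhat[p] <- .splitRhat(d)
    out$ess[p] <- .essTotal(d)
  }
  out
}

#' Fit the time-varying (repeated-outcome) multigroup BWQS model
#'
#' Same mixture mean structure as [fitLbwqsr()] with visit fixed
#' effects and a subject-level random intercept \code{u_i ~ N(0,
#' sigma_u^2)} (non-centered parameterization, \code{sigma_u ~
#' half-N(0, 1)}). \code{beta_g} is the visit-shared overall mixture
#' effect. With single-visit data the model falls back to the
#' cross-sectional fit with a warning.
#'
#' @param longOutcomes data.frame with columns \code{subject},
#'   \code{visit}, \code{y}; subjects must match the score rows by
#'   name or position.
#' @param quantScores \linkS4class{QuantScores} for the exposure window
#'   (one row per subject).
#' @param groups chemical-to-group map as in [buildDesign()].
#' @param covariates per-subject covariates (optional).
#' @param ... passed to [fitLbwqsr()] (prior, sampler settings, seed).
#' @return an \linkS4class{LbwqsrFit} with parameters including the
#'   visit effects (as \code{gamma[visit...]}) and \code{sigma_u}.
#' @export
fitTimeVarying <- function(longOutcomes, quantScores, groups,
                           covariates = NULL, ...) {
  stopifnot(all(c("subject", "visit", "y") %in% names(longOutcomes)))
  scores <- quantScores@scores
  subjNames <- rownames(scores)
  if (is.null(subjNames)) subjNames <- as.character(seq_len(nrow(scores)))
  if (length(unique(longOutcomes$visit)) < 2L) {
    warning("single-visit data: falling back to the cross-sectional model",
            call. = FALSE)
    idx <- match(subjNames, as.character(longOutcomes$subject))
    return(fitLbwqsr(buildDesign(quantScores, groups, covariates,
                                 outcome = longOutcomes$y[idx]), ...))
  }
  idx <- match(as.character(longOutcomes$subject), subjNames)
  if (any(is.na(idx)))
    stop("longOutcomes contains subjects absent from the score matrix",
         call. = FALSE)
  Qrep <- scores[idx, , drop = FALSE]
  covRep <- NULL
  visit <- factor(longOutcomes$visit)
  if (!is.null(covariates)) {
    covRep <- as.data.frame(covariates)[idx, , drop = FALSE]
    covRep$.visit <- visit
  } else {
    covRep <- data.frame(.visit = visit)
  }
  design <- buildDesign(Qrep, groups, covRep, outcome = longOutcomes$y,
                        subject = longOutcomes$subject,
                        outcomeName = "y(repeated)")
  fitLbwqsr(design, ...)
}

#' @describeIn summarizePosterior per-group posterior mean effect per
#'   quartile increase, central 95 percent credible interval, a
#'   significance flag (CrI excludes 0), and posterior-mean normalized
#'   weights attached as attribute \code{"weights"}.
#' @export
setMethod("summarizePosterior", "LbwqsrFit", function(object, ...) {
  grps <- levels(object@groups)
  rows <- lapply(grps, function(g) {
    d <- posteriorDraws(object, paste0("beta[", g, "]"))
    ci <- unname(quantile(d, c(0.025, 0.975)))
    data.frame(group = g, outcome = object@design@outcomeName,
               n = length(object@design@y),
               beta = mean(d), cri_low = ci[1], cri_high = ci[2],
               significant = ci[1] > 0 | ci[2] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "weights") <- mixtureWeights(object)
  out
})

#' @describeIn mixtureWeights posterior-mean weights per group,
#'   renormalized to sum exactly to 1.
#' @export
setMethod("mixtureWeights", "LbwqsrFit", function(object) {
  grps <- levels(object@groups)
  out <- setNames(vector("list", length(grps)), grps)
  for (g in grps) {
    chems <- names(object@groups)[object@groups == g]
    wm <- vapply(chems, function(ch)
      mean(posteriorDraws(object, paste0("w[", ch, "]"))), numeric(1))
    out[[g]] <- wm / sum(wm)
  }
  out
})
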