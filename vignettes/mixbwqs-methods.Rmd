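---
title: "Methods: penalized multigroup Bayesian WQS for chemical mixtures"
author: "mixBWQS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized multigroup Bayesian WQS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pregnant people are exposed to many nonpersistent endocrine-disrupting
chemicals (EDCs) at once — phthalates, phenols, parabens,
organophosphates, PAH metabolites, insecticide metabolites, DINCH —
and these co-occur in correlated groups. Estimating the joint effect
of such a mixture on perinatal outcomes (fetal growth z-scores,
Doppler pulsatility-index z-scores, angiogenic serum biomarkers) from
single-pollutant regressions is unsatisfying: estimates are unstable
under collinearity and there is no single "mixture effect" to report.
mixBWQS implements a penalized multigroup Bayesian Weighted Quantile
Sum (WQS) regression that addresses both problems, together with the
up- and downstream steps a complete analysis needs.

# The model

Each chemical $j$ in mixture group $g$ is quartile-scored: its log2
concentrations are ranked against their own empirical 25/50/75
percentiles, giving $q_{igj} \in \{0,1,2,3\}$ for subject $i$. The
outcome model is

$$ y_i = \alpha + \sum_{g=1}^{G} \beta_g \Big( \sum_{j=1}^{J_g} w_{gj}\, q_{igj} \Big) + \gamma' z_i + \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2), $$

with covariates $z_i$ and, per group, a weight vector $w_g$ on the
simplex. $\beta_g$ is the change in outcome per joint one-quartile
increase in group $g$'s chemicals, apportioned by the estimated
weights. All $G$ groups enter one model concurrently, which is what
distinguishes this multigroup formulation from fitting one WQS model
per mixture: shrinkage is shared and the groups compete for signal in
the presence of between-group correlation.

Priors:

* $w_g \sim \mathrm{Dirichlet}(a_0 \mathbf 1_{J_g})$, default $a_0 = 1$
  (uniform on the simplex). A group with one chemical has the point
  mass $w = 1$.
* Elastic-net shrinkage on group coefficients, sharing one scale:
  $p(\beta_g \mid \tau) \propto \exp\{-\lambda|\beta_g|/\tau -
  (1-\lambda)\beta_g^2/(2\tau^2)\}$ with mixing $\lambda \in [0,1]$
  (default $0.5$; $\lambda = 1$ is the LASSO/Laplace limit, $\lambda =
  0$ ridge/Gaussian). This family is a scale family in $\tau$: its
  normalizing constant is proportional to $\tau$, which the
  implementation accounts for so that the half-Cauchy$(0,1)$ hyperprior
  on the single shared $\tau$ is the one actually imposed. The shared
  $\tau$ is the "single origin" through which groups borrow strength:
  when most groups are null, $\tau$ shrinks and all coefficients are
  pulled toward zero; signs are never constrained.
* $\alpha, \gamma_k \sim N(0, 10^2)$, $\sigma \sim$ half-$N(0, 5)$.
* Repeated-outcome variant: visit fixed effects enter as covariates
  and a subject random intercept $u_i \sim N(0, \sigma_u^2)$ is added
  in non-centered form ($u_i = \sigma_u \tilde u_i$, $\tilde u_i \sim
  N(0,1)$), $\sigma_u \sim$ half-$N(0,1)$. The non-centered form keeps
  the sampler stable when the true $\sigma_u$ is at or near 0.

A flat-coefficient-prior mode (no $\tau$, improper flat prior on
$\beta$) exists for sensitivity analysis and validation: with weights
fixed at known values it reduces the model to Bayesian linear
regression, whose posterior means must coincide with ordinary least
squares on the known indices — a degenerate-limit oracle the test
suite checks.

# Posterior computation

The posterior is sampled with a No-U-Turn sampler written for this
package (Rcpp/RcppArmadillo): the slice-variant NUTS recursion with
dual-averaging step-size adaptation (target acceptance 0.9, cap at
tree depth 10) and windowed diagonal mass-matrix adaptation, over the
model's analytic log-posterior gradient. Simplex weights are sampled
through the stick-breaking bijection with its log-Jacobian; $\tau$,
$\sigma$, $\sigma_u$ on the log scale. The Laplace component of the
elastic-net prior is non-differentiable only on a measure-zero set;
the subgradient at 0 is taken as 0, the standard practice for
gradient-based samplers with Laplace priors. The gradient is verified
against finite differences in the unit tests, and the whole sampler is
cross-checked against an independent Gibbs implementation (JAGS, via
the zeros trick for the elastic-net density) on a small two-group
model.

Defaults are 4 chains of 1000 warmup + 1000 retained draws, with a
mandatory seed; chain seeds derive deterministically from it and the
sampler uses its own counter-based RNG, so fits are bit-reproducible.
After sampling, split R-hat and effective sample sizes are computed
for every parameter; a fit is flagged when any split R-hat $\ge 1.05$,
total ESS $< 100$ per chain, or more than 5% of transitions diverge.

# Exposure processing

* **Below-LOD imputation.** Non-detected cells receive exactly one
  imputed value strictly inside $(0, \mathrm{LOD})$, drawn from a
  log-normal fitted to the chemical's detected values and truncated at
  the LOD (inverse-CDF sampling). This preserves the shape of the left
  tail, the standard choice for biomonitoring data. A deterministic
  LOD$/\sqrt2$ fill-in is available as a sensitivity option, and the
  truncated fit falls back to it when fewer than three detected values
  exist. Fitting the log-normal to detected values only ignores the
  left-truncation of that subsample; at the detection frequencies the
  panel targets ($\ge 50\%$, mostly $\ge 80\%$) the resulting bias in
  the imputed tail is immaterial to quartile scores.
* **Quartile scoring.** Cutpoints are linear-interpolation empirical
  percentiles (R type 7); the score is the number of cutpoints $\le$
  the value, so ties promote upward and a constant chemical scores 3
  everywhere. Scoring is invariant to strictly monotone transforms —
  log2 before ranking changes nothing, a property the tests assert.
* **Descriptives.** Spearman correlations use average ranks and
  pairwise-complete observations; a zero-variance chemical yields NA,
  never 0. The ICC between the two sampling windows is the one-way
  random-effects estimator for two occasions,
  $(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+\mathrm{MSW})$, on log2
  values of complete pairs; negative estimates are reported as
  computed (a floor at 0 is optional), because truncation hides
  information about assay noise.

# Outcome standardization

Gestational-age z-scores interpolate a tabulated reference chart
linearly in GA for both the median and the SD; extrapolation outside
the chart grid is refused outright — reference-chart misuse outside
support is a known failure mode. Multiples of the median (MoM) divide
each biomarker value by its GA-specific median from a $\tau = 0.5$
quantile regression of $\log(\text{value})$ on GA (linear by default,
polynomial degree configurable). Because no linear-programming
quantile-regression routine is part of this package's dependency set,
the median regression minimizes the absolute-deviation loss with a
restarted Nelder-Mead search from the OLS start; with 2-3 parameters
this converges reliably and the median calibration (half the sample
below MoM 1) is tested.

For the sFlt-1/PlGF ratio the package computes the ratio, log2
transforms it, then GA-standardizes — the order in which these steps
are conventionally reported. That order requires the log2 ratio to be
positive (ratios above 1, typical at the 32-week draw); the
alternative order (MoM of the raw ratio, then log2) is well defined
for any positive ratio and is available via `order = "mom-then-log2"`.

# Downstream inference

The mixture index multiplies each chemical's log2 concentration by its
posterior-mean normalized weight and sums within the group. Fetal-sex
effect modification is tested with one adjusted linear model carrying
an index-by-sex product term (Wald p), with sex-specific slopes from
stratified fits. Mediation uses the product of coefficients: $a$ from
the adjusted mediator model, $b$ and the direct effect from the
adjusted outcome model; ACME $= ab$, total $=$ ACME $+$ direct, which
in this linear no-interaction setting equals the total-effect OLS
coefficient exactly — an algebraic identity the tests verify to
$10^{-10}$. Inference is a nonparametric bootstrap over subjects
(percentile intervals, two-sided bootstrap p for the ACME; the
analysis convention is 10,000 resamples). The proportion mediated is
ACME/total and is reported as missing when the total effect is
indistinguishable from zero. A fully deterministic
exposure-mediator-outcome chain makes mediator and exposure exactly
collinear, leaving the decomposition unidentified; `mediate()` raises
an informative error rather than returning an arbitrary solution.

# The synthetic cohort generator

The generator exists so that every estimator above can be tested
against known truth. It emulates:

* 30 metabolites in 8 groups (9 HMWP, 3 LMWP, 2 DINCH, 2 insecticide,
  4 PAH, 3 OP, 4 phenol, 3 paraben) with log-normal concentrations
  whose medians span roughly 0.5-40 ng/mL;
* block correlation on the log scale — strong within groups (default
  0.6), weak between (default 0.15), with an elevated LMWP-HMWP
  cross-block (default 0.45), the qualitative pattern seen in
  biomonitoring correlation heatmaps. The published source reports
  between-group correlations only qualitatively, so these defaults are
  chosen once as field-realistic values, not calibrated to any table;
* two sampling windows with analyte-specific ICCs in 0.1-0.65 (low
  for PAH/OP/insecticide metabolites, higher for MEP, triclosan,
  parabens). The two-visit covariance is built as
  $[R, DRD; D R D, R]$ with $D = \mathrm{diag}(\sqrt{\mathrm{icc}})$,
  so same-visit correlations equal $R$ exactly and visit pairs of
  chemical $j$ correlate at exactly $\mathrm{icc}_j$. This matrix is
  factorized by eigendecomposition (PSD allowed: icc $= 1$ is legal
  and makes the visits coincide);
* LOD censoring at a configurable quantile of each marginal, stored as
  a missing value plus a non-detect flag with the LOD kept per
  chemical — fill-in is the processing module's job;
* complete covariates patterned on a European urban pregnancy cohort
  (age 34.3 $\pm$ 4.4, ~60% nulliparous, ~10% smoking, balanced fetal
  sex), deliberately without missingness: covariate imputation is out
  of scope, so the generator produces the single complete table the
  models consume;
* outcomes drawn from exactly the WQS mean structure above (the
  data-generating mirror of the fitted model), repeated outcomes with
  a shared subject intercept, and an exposure-mediator-outcome triplet
  for mediation.

Every cohort carries its `SimTruth`; recovery tests consume only the
cohort plus this record. What the generator does **not** emulate — and
hence what passing tests cannot certify — includes real missingness
patterns, creatinine/dilution adjustment, model misspecification
(nonlinear or interacting exposure effects), unmeasured confounding,
and real reference-chart shapes (the tabulated charts here are smooth
toy curves). Recovery results on this cohort validate the estimators,
not the substantive findings obtainable from any particular real data
set.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant chemicals score 3
(tie rule) and yield NA Spearman entries; single-visit data demote the
time-varying model to the cross-sectional fit with a warning;
rank-deficient regression designs raise errors naming the aliased
columns. Reported weights are posterior means renormalized to sum to
exactly 1.

The validation suite exercises: one full recovery fit at $n = 500$
with 4 chains of 1000+1000 draws; null-calibration and
weight-identification studies across repeated cohorts at $n = 500$ and
$n = 1000$ with 2 shorter chains each (the credible intervals and
weight rankings these studies read off are stable at that chain
length); mediation identities at $n = 5000$; interaction-test
calibration over 200 null simulations at $n = 2000$; and ICC, z-score
and MoM calibration at $n = 2000$. The same study sizes are recomputed
from scratch by `scripts/acceptance.R`.

# Known limitations

* Weights are weakly identified when a group's $\beta_g$ is near zero;
  their posteriors then revert toward the Dirichlet prior. This is
  inherent to WQS-type models, not an implementation artifact.
* The elastic-net prior's hyperparameters ($\lambda$, the Dirichlet
  concentration, the $\tau$ hyperprior) are modelling choices exposed
  in the interface, with the defaults above; no attempt is made to
  infer $\lambda$.
* Quartile scoring discards within-quartile dose information by
  design; effects are per quartile increase.
* The mediation estimator presumes no exposure-mediator interaction
  and the usual sequential-ignorability assumptions; no sensitivity
  analysis for their violation is included.
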