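---
title: "Methods: generalized SEM mediation of working hours on near-miss incidents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized SEM mediation of working hours on near-miss incidents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gsemmed` implements a generalized structural equation model (GSEM) for the
mediation of weekly working hours on the occurrence of near-miss incidents
among full-time workers. Working hours are a four-level categorical exposure
(35–40, 41–50, 51–60, ≥61 h/w) encoded as dummy variables against the 35–40
h/w reference. Three continuous mediators — job-related stress (BJSQ job
stressors total, 17–68), sleep problems (PSQI total, 0–21) and depressive
symptoms (CES-D total, 0–60) — are modelled as linear functions of the
exposure dummies. The mediators load on a latent *fatigue* variable whose
loading on the outcome is fixed at 1.00 to set the latent scale, and the
binary near-miss outcome follows a logistic regression on the exposure
dummies, fatigue, and two covariates (male sex, age ≥ 35):

$$
\begin{aligned}
M_k &= \alpha_k + \sum_\ell a_{\ell k}\, X_\ell + \varepsilon_k,
  & \varepsilon &\sim N(0, \Sigma),\\
F &= \sum_k b_k M_k + \zeta, & \zeta &\sim N(0, \psi),\\
\operatorname{logit} P(Y = 1) &= \nu + \sum_\ell d_\ell X_\ell
  + 1.00 \cdot F + \gamma_1\,\mathrm{male} + \gamma_2\,\mathrm{age{\ge}35}.
\end{aligned}
$$

All mediator coefficients are reported on the *standardized* scale:
continuous mediators are z-scored with the sample SD (denominator $n-1$),
dummies are left raw, and the outcome equation is on the log-odds scale.
This is the convention under which the published effect table is exactly the
exponential of products of the published coefficient table, which is how the
worked example in `README.md` reproduces it.

### Effects

Every simple directed path from an exposure dummy to the outcome contributes
the product of its edge coefficients (fixed constraints included) on the
log-odds scale. Indirect effects are grouped by the **first mediator** on the
path — so in the sensitivity variant with a stress → sleep edge, the path
$X \to \text{stress} \to \text{sleep} \to F \to Y$ counts toward the stress
group. The total effect is direct plus the sum of all indirect effects, and
odds ratios are obtained by one exponentiation at the end, which makes
$\mathrm{OR}_{\text{total}} = \mathrm{OR}_{\text{direct}} \times \prod_k
\mathrm{OR}_{\text{indirect},k}$ hold to machine precision. Working on the
coefficient scale first also matches the significance rule (a 95% CI for a
difference measure that does not include 0); a per-full-path breakdown is
retained in `attr(effects, "path_contributions")` for transparency.

This is the classical product-of-coefficients decomposition. Counterfactual
(natural) effect definitions with exposure–mediator interaction are out of
scope.

### Estimation modes

**Composite (default, `psi = 0`).** Fatigue is a deterministic weighted sum
of the standardized mediators. The joint likelihood then factorizes into one
Gaussian linear equation per mediator (fitted by `lm`) and a single logistic
outcome equation (fitted by `glm`); because the fatigue loading is fixed at
1.00, the mediator coefficients of the logistic fit *are* the mediator →
fatigue loadings $b_k$. The factorization is asserted in the tests
(`loglik == loglik_mediators + loglik_outcome`, exactly). Composite mode is
the default because the published direct/indirect/total odds ratios equal
the exponentials of the products of the published coefficients to two
decimals, which holds only when fatigue carries no disturbance.

**Latent disturbance.** Fatigue keeps its own normal disturbance
$\zeta \sim N(0, \psi)$, which is integrated out of the outcome likelihood
by Gauss–Hermite quadrature (21 nodes by default; estimates move by less
than $10^{-4}$ between 21 and 41 nodes on calibrated synthetic data). The
marginal likelihood is maximized by profiling over the disturbance scale
with a damped-Newton inner fit using analytic gradients and Hessians.

A caution that the package makes explicit: with a *single* binary outcome
measurement per respondent, $\psi$ is identified only through the difference
in shape between a logistic and a logistic-normal marginal link. Profiling
the likelihood over $\sigma = \sqrt{\psi} \in [0, 3]$ on calibrated
synthetic data with $n = 10^5$ moves the log-likelihood by well under one
unit — regardless of the generating $\psi$. The estimator therefore keeps a
positive $\hat\psi$ only when it improves the log-likelihood beyond the 5%
critical value of the boundary likelihood-ratio mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (a gain of 1.35); otherwise it reports
the boundary fit $\hat\psi = 0$ with `meta$psi_boundary = TRUE` and the
achieved gain in `meta$psi_lrt_gain`. Users should treat $\hat\psi$ as
essentially non-estimable in this design and regard the latent-disturbance
mode as a sensitivity wrapper around the composite fit, not as a way to
learn $\psi$. Standard errors are omitted in this mode; the bootstrap is the
inferential instrument.

**Missing data** are handled by listwise deletion over the model variables,
mirroring the analyzed-population definition (full-time respondents with a
near-miss response); the eligibility filter logs exclusion counts that sum
to the input row count.

## Inference

Nonparametric bootstrap: whole respondents are resampled with replacement
(preserving the joint mediator–outcome structure), every equation is refit,
the decomposition recomputed, and each coefficient and effect is summarized
by a percentile CI. Choices that matter:

* `B = 1000` by default. The replicate count behind the published intervals
  is not stated; 1000 is the field's conventional default and is
  configurable everywhere.
* Quantile rule: order-statistic quantiles with linear interpolation (R's
  type 7). At small `B` percentile bounds depend on this rule, so it is
  pinned down and tested. When $(B-1)/40$ is an integer the 2.5/97.5%
  bounds are exact order statistics and exponentiating the log-scale bounds
  equals the bounds of the exponentiated replicates exactly; otherwise the
  two differ only within interpolation.
* Significance: a quantity is flagged iff its coefficient-scale CI excludes
  0 strictly — a bound exactly at 0 is *not* significant.
* Failed replicates (separation or non-convergence, typical of very small
  exposure cells) are dropped and counted, never imputed; if more than 5% of
  replicates fail the run aborts, since a fit that fragile should not be
  summarized by quantiles. Stratified resampling by exposure category
  (`stratify_by = "exposure"`) is available to stabilize small strata in
  subgroup runs.

## The synthetic survey generator

No public version of the original survey exists, so the generator emulates
its statistical structure: margins match the published descriptive table
(hour-category counts 507/665/170/148 out of 1490, 76.7% female, 64.5% aged
≥ 35, 37.1% night/shift work, experience categories 19.0/32.3/48.7%), the
mediator instrument moments are 44.0 (6.3), 5.8 (3.0) and 16.5 (9.7), the
path coefficients default to the published standardized point estimates, and
the outcome intercept is calibrated so the marginal near-miss prevalence is
49.1%.

Generator mechanics and the reasoning behind them:

* Mediators are generated on the standardized scale and mapped to instrument
  scale afterwards (`raw = mean + sd * z`, rounded to integers, clipped to
  the legal range), because the generating coefficients are standardized.
  Exposure dummies are centered in the mediator equations and the residual
  variance is set to $1 - \mathrm{Var}(\text{systematic part})$, so each
  standardized mediator has marginal mean 0 and variance 1 and the
  instrument-scale moments reproduce the descriptive table. Rounding and
  clipping happen last and are a deliberate, slight source of
  miscalibration: rounding adds variance $1/12$ of a scale point and
  clipping mainly affects the depression score (about 4–5% of its mass sits
  below 0 before clipping). Parameter recovery at $n = 2 \times 10^5$ stays
  within ±0.03 despite both.
* The intercept $\nu$ is found by monotone root-finding (`uniroot` on
  $[-10, 10]$) of the simulated marginal prevalence as a function of $\nu$,
  computed over a fixed-seed draw of $4 \times 10^5$ linear predictors,
  which keeps the calibration error around ±0.002.
* Mediator residual correlations default to the identity; the study reports
  no residual correlations, so the identity is an explicit assumption, and
  `residual_corr` accepts any valid correlation matrix for stress tests.
* Covariates are drawn independently of exposure by default (no joint
  distribution is published); `p_male_by_hours` / `p_age_ge35_by_hours`
  allow exposure-dependent covariates for confounding stress tests.
* Work experience is drawn as a category (≤3, 4–10, ≥11 years) with the
  published probabilities, then an integer year uniformly within category
  (11–40 for the open-ended top category), supporting the subgroup runner.
  The fatigue-recovery score (1–4) is uniform, as no distribution is
  published; it only matters for the covariate sensitivity variant.
* `psi` defaults to 0, consistent with composite mode being the reference
  analysis.

What passing tests on this generator do **not** show about real data: the
generator has no item-level questionnaire structure, no panel-recruitment or
nonresponse mechanism, no exposure–covariate dependence by default, linear
mediator equations with normal residuals, and an exactly logistic outcome.
Recovery and coverage results demonstrate internal correctness of the
estimator under the assumed structure, not robustness to violations of it.

## Numerical choices

* Logistic equations: `stats::glm`/`glm.fit` (IRLS) with tolerance $10^{-8}$
  and up to 100 iterations; separation is detected by diverging coefficients
  (|coef| > 30) and raised, never silently dropped. The test suite checks
  the fit against an independently written IRLS to $10^{-8}$.
* Bootstrap refits reuse precomputed design matrices and warm-start the IRLS
  at the full-sample estimates.
* Path enumeration is an exhaustive recursive walk over simple paths,
  returned in lexicographic order so enumeration is deterministic; tests
  compare it against `igraph::all_simple_paths`.
* All simulation entry points take an explicit integer seed, restore the
  caller's RNG state, and byte-identical outputs for identical seed + config
  are asserted in the tests (including the full study pipeline).
* Degenerate inputs: zero-variance mediators, subgroups under 50 rows or
  with a constant outcome, empty bootstrap draws, unbracketed calibration
  roots and cyclic model variants all raise or warn with specific messages.

## Problem sizes used by the test suite

Chosen to make the statistical assertions sharp while keeping a full run
modest on one core: parameter recovery at $n = 2\times10^5$ (±0.03),
generator calibration at $n = 10^5$ (±0.5 percentage points),
latent-boundary behaviour at $n = 10^5$, bootstrap coverage over 200
simulated studies of $n = 1490$ with $B = 400$ (coverage asserted within
95% ± 4%), CI-shrinkage at $n \in \{500, 2000, 8000\}$ with $B = 150$, and
oracle comparisons at $n \le 3000$.

## Known limitations

* The latent disturbance variance is effectively non-estimable with one
  binary outcome per respondent (see above); composite mode is the
  meaningful default.
* Model-fit indices (CFI, RMSEA, …) are not provided: they are not defined
  for this model class with a maximum-likelihood logistic outcome.
* The decomposition is product-of-coefficients; it does not address
  exposure–mediator interaction or counterfactual identifiability beyond
  the model's own assumptions.
* Survey weights and design-based variance estimation are out of scope.
* Only one latent variable and recursive (acyclic) structures are
  supported; mediator → outcome edges that bypass the latent are rejected
  by design.
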