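# gsemmed

Generalized structural equation mediation analysis of long working hours on
near-miss incidents.

## The problem

Near-miss incidents — unplanned events that could have caused injury but did
not — are leading indicators of serious occupational accidents, and they are
common among healthcare professionals working long hours. The open question
this package addresses is *how* long hours raise near-miss risk: directly,
or indirectly through job-related stress, poor sleep and depressive
symptoms. Quantifying the split matters because the indirect channels are
the ones amenable to workplace intervention short of cutting hours.

`gsemmed` is aimed at occupational epidemiologists and biostatisticians who
want a reproducible, tested implementation of this analysis: a generalized
structural equation model (GSEM) with a categorical exposure, continuous
mediators, a latent fatigue composite and a binary outcome, plus a
calibrated synthetic-survey generator so the full pipeline can be exercised
and validated without access to restricted survey data.

## The model

Weekly working hours enter as dummies $X_\ell$ for 41–50, 51–60 and ≥61 h/w
against the 35–40 h/w reference. Three questionnaire totals — job-related
stress (BJSQ, 17–68), sleep problems (PSQI, 0–21) and depressive symptoms
(CES-D, 0–60) — are mediators $M_k$, z-scored and modelled linearly; they
load on a latent fatigue variable $F$ whose loading on the outcome is fixed
at 1.00 to set its scale; the binary near-miss outcome $Y$ is logistic:

$$
M_k = \alpha_k + \textstyle\sum_\ell a_{\ell k} X_\ell + \varepsilon_k,
\qquad
F = \textstyle\sum_k b_k M_k + \zeta,
$$
$$
\operatorname{logit} P(Y=1) = \nu + \textstyle\sum_\ell d_\ell X_\ell
 + 1.00\,F + \gamma_1\,\text{male} + \gamma_2\,\text{age}{\ge}35 .
$$

Each exposure→outcome path contributes the product of its edge coefficients
on the log-odds scale; indirect effects are grouped by the first mediator on
the path; the total effect is direct + Σ indirect, and odds ratios are
`exp()` of these, so `OR_total = OR_direct × Π OR_indirect` exactly.
Percentile-bootstrap CIs (respondent-level resampling and full refits) carry
the inference; an effect is significant when its coefficient-scale 95% CI
excludes 0. See `vignettes/gsemmed-methods.Rmd` for assumptions, numerical
choices and limitations (including why the latent disturbance variance is
effectively non-estimable in this design).

## Worked example

Feeding the published standardized point estimates through the decomposition
reproduces the published effect table:

```r
library(gsemmed)
model <- default_model()          # 3 dummies, 3 mediators, latent fatigue
published <- coef_table(          # standardized point estimates
  source   = c("hours41_50","hours51_60","hours61plus",
               "hours41_50","hours51_60","hours61plus",
               "hours41_50","hours51_60","hours61plus",
               "hours41_50","hours51_60","hours61plus",
               "job_stress","sleep","depression","fatigue","male","age_ge35"),
  target   = c(rep("near_miss",3), rep("job_stress",3), rep("sleep",3),
               rep("depression",3), rep("fatigue",3),
               "near_miss","near_miss","near_miss"),
  estimate = c(0.100,0.087,0.016, 0.290,0.556,0.690, 0.056,0.168,0.263,
               0.007,0.142,0.362, 0.397,0.239,-0.021, 1.00, 0.070,-0.157),
  fixed    = c(rep(FALSE,15), TRUE, FALSE, FALSE))
decompose_effects(published, enumerate_paths(model))
#> Effect decomposition (odds-ratio scale):
#>  level           direct indirect_depression indirect_job_stress
#>  35-40 1.00 (reference)    1.00 (reference)    1.00 (reference)
#>  41-50             1.11                1.00                1.12
#>  51-60             1.09                1.00                1.25
#>   >=61             1.02                0.99                1.32
#>    indirect_sleep            total
#>  1.00 (reference) 1.00 (reference)
#>              1.01             1.26
#>              1.04             1.41
#>              1.06             1.41
```

Reading across the 41–50 h/w row: working 41–50 h/w instead of 35–40 h/w
multiplies the odds of a near-miss by 1.11 directly, by 1.12 through the
job-stress→fatigue channel, and by 1.26 in total; the stress channel, not
the direct path, carries most of the effect, and that pattern strengthens
with longer hours.

The same pipeline on synthetic data, with bootstrap CIs (the generator's
defaults are calibrated to the published margins and coefficients):

```r
cfg  <- default_config()                       # intercept auto-calibrated
d    <- simulate_survey(cfg, n = 1490, seed = 3)
boot <- bootstrap_gsem(d, B = 200, seed = 11)
boot
#> Bootstrap: B = 200 (failed: 0), seed = 11, 95% percentile CIs
#>  level            direct indirect_depression indirect_job_stress
#>  35-40  1.00 (reference)    1.00 (reference)    1.00 (reference)
#>  41-50 1.21 (0.95, 1.55)   1.00 (0.99, 1.01)   1.14 (1.07, 1.23)
#>  51-60 1.66 (1.14, 2.51)   1.00 (0.98, 1.02)   1.21 (1.12, 1.30)
#>   >=61 1.35 (0.91, 2.09)   1.00 (0.96, 1.05)   1.36 (1.25, 1.52)
#>     indirect_sleep             total
#>   1.00 (reference)  1.00 (reference)
#>  1.02 (1.00, 1.05)  1.41 (1.12, 1.87)
#>  1.06 (1.02, 1.11)  2.13 (1.51, 3.21)
#>  1.05 (1.01, 1.12)  1.94 (1.28, 2.89)
```

At a single simulated study of n = 1490 the point estimates scatter around
the generating values (direct effects are noisy; the indirect-via-stress
CIs exclude 1, as expected from the generating path product); the test
suite checks calibration properly, with parameter recovery at n = 200,000
and a 200-replication coverage study.

`run_study()` wraps the whole analysis (eligibility filter → descriptive
table → fit → decomposition → bootstrap → subgroup/sensitivity variants)
and writes deterministic CSV reports; `inst/cli/gsemmed.R` exposes it as a
command line (`simulate`, `fit`, `decompose`, `bootstrap`, `run`,
`report`).

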