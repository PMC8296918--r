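Package: gsemmed
Title: Generalized Structural Equation Mediation of Working Hours on
    Near-Miss Incidents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a generalized structural equation model for mediation of a
    categorical exposure (weekly working-hour bands) on a binary safety
    outcome (near-miss incidents) through continuous mediators (job-related
    stress, sleep problems, depressive symptoms) combined into a latent
    fatigue composite with a fixed unit loading. Provides declarative model
    graphs with validation and exhaustive path enumeration, composite and
    latent-disturbance (Gauss-Hermite marginal likelihood) estimation,
    product-of-coefficients decomposition of direct, indirect and total
    effects on the odds-ratio scale, nonparametric bootstrap percentile
    confidence intervals, a calibrated synthetic survey generator, and an
    end-to-end study pipeline with subgroup and sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
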