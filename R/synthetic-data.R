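# Synthetic person-level survey generator. Emulates the cross-sectional
# survey the model is designed for: categorical weekly working hours,
# demographics, three questionnaire totals (BJSQ job stressors 17-68, PSQI
# 0-21, CES-D 0-60), and a binary near-miss outcome generated through the
# mediation structure (hours -> mediators -> fatigue composite -> logistic
# outcome). Defaults are calibrated to the published marginals and
# standardized path coefficients, so estimation can be exercised and tested
# without access to the (non-shareable) original data.

MEDIATORS <- data.frame(
  node = c("job_stress", "sleep", "depression"),
  column = c("job_stress_total", "sleep_total", "depression_total"),
  raw_mean = c(44.0, 5.8, 16.5),
  raw_sd = c(6.3, 3.0, 9.7),
  range_min = c(17, 0, 0),
  range_max = c(68, 21, 60),
  stringsAsFactors = FALSE)

HOUR_LEVELS <- c("35-40", "41-50", "51-60", ">=61")
EXPERIENCE_LEVELS <- c("le3", "4-10", "ge11")

#' Default generator configuration
#'
#' Returns a `gsem_config` calibrated to the published study: n = 1490
#' respondents; working-hour category probabilities (507, 665, 170, 148)/1490
#' (i.e. 34.0/44.6/11.4/9.9%); 76.7% female; 64.5% aged >= 35; experience
#' categories <=3 / 4-10 / >=11 years with probabilities 19.0/32.3/48.7%;
#' 37.1% night/shift work; mediator instrument-scale moments 44.0 (6.3) for
#' job stress, 5.8 (3.0) for sleep, 16.5 (9.7) for depression; standardized
#' path coefficients equal to the published point estimates; and the outcome
#' intercept calibrated by [calibrate_intercept()] so the marginal near-miss
#' prevalence is 49.1%.
#'
#' @param n number of respondents to simulate.
#' @param seed integer seed stored in the config and used by
#'   [simulate_survey()].
#' @param calibrate if `TRUE` (default) the outcome intercept `nu` is set by
#'   [calibrate_intercept()]; if `FALSE`, `nu` is left `NA` (useful when the
#'   caller will set coefficients and calibrate manually).
#' @return a `gsem_config` list; see Details for fields.
#'
#' @details Fields: `n`, `seed`; margins `p_hours`, `p_female`, `p_age_ge35`,
#' `p_experience`, `p_nightshift`, `p_recovery`; `mediators` (raw moments and
#' legal ranges); coefficient blocks `a` (exposure level x mediator,
#' standardized), `b` (mediator -> fatigue loadings), `d` (direct exposure ->
#' outcome log-odds), `gamma` (covariate -> outcome log-odds), `loading`
#' (fixed fatigue -> outcome coefficient), `nu` (outcome intercept,
#' log-odds), `target_prevalence`; `residual_corr` (3x3 mediator residual
#' correlation, identity by default), `psi` (latent disturbance variance,
#' 0 = deterministic composite). Optional hooks `p_male_by_hours` and
#' `p_age_ge35_by_hours` (length-4 probability vectors) make covariates
#' depend on exposure for confounding stress tests.
#' @export
default_config <- function(n = 1490, seed = 20181001L, calibrate = TRUE) {
  a <- rbind(hours41_50  = c(0.290, 0.056, 0.007),
             hours51_60  = c(0.556, 0.168, 0.142),
             hours61plus = c(0.690, 0.263, 0.362))
  colnames(a) <- MEDIATORS$node
  cfg <- structure(list(
    n = as.integer(n),
    seed = as.integer(seed),
    p_hours = setNames(c(507, 665, 170, 148) / 1490, HOUR_LEVELS),
    p_female = 1143 / 1490,
    p_age_ge35 = 961 / 1490,
    p_experience = setNames(c(283, 481, 726) / 1490, EXPERIENCE_LEVELS),
    p_nightshift = 553 / 1490,
    p_recovery = rep(0.25, 4),
    p_male_by_hours = NULL,
    p_age_ge35_by_hours = NULL,
    mediators = MEDIATORS,
    a = a,
    b = c(job_stress = 0.397, sleep = 0.239, depression = -0.021),
    d = c(hours41_50 = 0.100, hours51_60 = 0.087, hours61plus = 0.016),
    gamma = c(male = 0.070, age_ge35 = -0.157),
    loading = 1.00,
    nu = NA_real_,
    target_prevalence = 732 / 1490,
    residual_corr = diag(3),
    psi = 0,
    level_nodes = setNames(rownames(a), HOUR_LEVELS[-1])
  ), class = "gsem_config")
  if (calibrate)
    cfg$nu <- calibrate_intercept(cfg, cfg$target_prevalence)
  cfg
}

#' Validate a generator configuration
#'
#' @param config a `gsem_config`.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (!is.numeric(config$n) || config$n < 1) v <- c(v, "n must be >= 1")
  if (abs(sum(config$p_hours) - 1) > 1e-8)
    v <- c(v, "p_hours must sum to 1")
  props <- c(config$p_hours, config$p_female, config$p_age_ge35,
             config$p_experience, config$p_nightshift, config$p_recovery)
  if (any(props < 0 | props > 1))
    v <- c(v, "all proportions must be in [0, 1]")
  if (abs(sum(config$p_experience) - 1) > 1e-8)
    v <- c(v, "p_experience must sum to 1")
  R <- config$residual_corr
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-10))
    v <- c(v, "residual_corr must be symmetric with unit diagonal")
  else if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    v <- c(v, "residual_corr must be positive semi-definite")
  if (config$psi < 0) v <- c(v, "psi must be >= 0")
  if (any(config$mediators$raw_sd <= 0)) v <- c(v, "raw_sd must be > 0")
  if (!all(dim(config$a) == c(length(config$d), nrow(config$mediators))))
    v <- c(v, "a must be (levels x mediators)")
  if (length(config$b) != nrow(config$mediators))
    v <- c(v, "b must have one loading per mediator")
  v
}

assert_valid_config <- function(config) {
  v <- validate_config(config)
  if (length(v))
    stopf("invalid generator config:\n  - %s", paste(v, collapse = "\n  - "))
  invisible(config)
}

# Residual SDs that make each standardized mediator have marginal variance 1:
# the systematic part sum_l a[l,k] * (X_l - p_l) has variance
# sum p a^2 - (sum p a)^2 over the multinomial exposure, and the residual
# absorbs the remainder.
mediator_residual_sd <- function(config) {
  p <- config$p_hours[-1]                       # dummy probabilities
  v_sys <- colSums(config$a^2 * p) - colSums(config$a * p)^2
  if (any(v_sys >= 1))
    stopf("systematic mediator variance >= 1; standardized scale impossible")
  sqrt(1 - v_sys)
}

# Core generative draw. Returns covariate/exposure draws, standardized
# mediator values, and the outcome linear predictor WITHOUT the intercept nu,
# so the same routine backs both simulate_survey() and intercept calibration.
simulate_core <- function(config, n, seed) {
  with_seed(seed, {
    hours <- factor(sample(HOUR_LEVELS, n, replace = TRUE,
                           prob = config$p_hours), levels = HOUR_LEVELS)
    X <- vapply(HOUR_LEVELS[-1], function(l) as.numeric(hours == l),
                numeric(n))
    if (!is.matrix(X)) X <- matrix(X, nrow = n, ncol = 3)
    colnames(X) <- config$level_nodes[HOUR_LEVELS[-1]]

    p_male <- if (!is.null(config$p_male_by_hours))
      config$p_male_by_hours[as.integer(hours)] else 1 - config$p_female
    male <- rbinom(n, 1, p_male)
    p_age <- if (!is.null(config$p_age_ge35_by_hours))
      config$p_age_ge35_by_hours[as.integer(hours)] else config$p_age_ge35
    age_ge35 <- rbinom(n, 1, p_age)
    night_shift <- rbinom(n, 1, config$p_nightshift)
    exp_cat <- sample(EXPERIENCE_LEVELS, n, replace = TRUE,
                      prob = config$p_experience)
    experience_years <- ifelse(exp_cat == "le3", sample(0:3, n, TRUE),
                        ifelse(exp_cat == "4-10", sample(4:10, n, TRUE),
                               sample(11:40, n, TRUE)))
    recovery <- sample(1:4, n, replace = TRUE, prob = config$p_recovery)

    Xc <- sweep(X, 2, config$p_hours[-1])       # centered dummies
    sd_eps <- mediator_residual_sd(config)
    Z <- matrix(rnorm(n * 3), n, 3) %*% chol(config$residual_corr)
    eps <- sweep(Z, 2, sd_eps, `*`)
    M <- Xc %*% config$a + eps                  # standardized mediators
    colnames(M) <- config$mediators$node

    zeta <- if (config$psi > 0) rnorm(n, 0, sqrt(config$psi)) else 0
    fatigue <- drop(M %*% config$b) + zeta

    lp <- drop(X %*% config$d[colnames(X)]) + config$loading * fatigue +
      config$gamma[["male"]] * male + config$gamma[["age_ge35"]] * age_ge35
    if ("night_shift" %in% names(config$gamma))
      lp <- lp + config$gamma[["night_shift"]] * night_shift
    if ("fatigue_recovery" %in% names(config$gamma))
      lp <- lp + config$gamma[["fatigue_recovery"]] * recovery

    list(hours = hours, male = male, age_ge35 = age_ge35,
         night_shift = night_shift, experience_years = experience_years,
         recovery = recovery, M = M, lp_no_nu = lp)
  })
}

#' Calibrate the outcome intercept to a target prevalence
#'
#' The published tables report the marginal outcome prevalence but no
#' intercept, so the generator finds the log-odds intercept `nu` at which the
#' marginal simulated near-miss prevalence equals the target. The marginal
#' prevalence `mean(plogis(nu + lp))` is computed over a large fixed-seed
#' draw of non-intercept linear predictors and is strictly increasing in
#' `nu`, so the root is found by [stats::uniroot()] on [-10, 10].
#'
#' @param config a `gsem_config` (its `nu` is ignored).
#' @param target_prevalence target marginal outcome proportion in (0, 1).
#' @param n_calib Monte Carlo sample size for the prevalence curve; the
#'   default 4e5 keeps the calibration error around +/-0.002.
#' @return the calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, target_prevalence = config$target_prevalence,
                                n_calib = 400000L) {
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stopf("target_prevalence must be in (0, 1)")
  v <- setdiff(validate_config(config), character(0))
  if (length(v)) stopf("invalid generator config: %s", paste(v, collapse = "; "))
  lp <- simulate_core(config, n_calib, seed = config$seed)$lp_no_nu
  f <- function(nu) mean(plogis(nu + lp)) - target_prevalence
  if (f(-10) > 0 || f(10) < 0)
    stopf("intercept root not bracketed in [-10, 10]")
  uniroot(f, c(-10, 10), tol = 1e-8)$root
}

#' Simulate a synthetic survey dataset
#'
#' Draws exposure, demographics and experience independently from their
#' configured margins; draws standardized mediator values from the linear
#' exposure model with correlated normal residuals scaled so each mediator
#' has marginal mean 0 and variance 1; maps mediators to instrument scale
#' (mean + sd * z), rounds to integers and clips to the legal instrument
#' range; forms the fatigue composite `F = sum(b * M) + zeta` with
#' `zeta ~ N(0, psi)`; and draws the binary near-miss outcome from a logistic
#' model with intercept `nu`, direct exposure effects, the fixed fatigue
#' loading, and covariate effects. Deterministic given `seed`.
#'
#' @param config a valid `gsem_config` with a finite `nu` (see
#'   [calibrate_intercept()]).
#' @param n,seed optional overrides of `config$n` / `config$seed`.
#' @return a data.frame of survey records: `id`, `hours_category`, `sex`,
#'   `age_group`, `experience_years`, `night_shift`, `job_stress_total`,
#'   `sleep_total`, `depression_total`, `fatigue_recovery`, `near_miss`; the
#'   seed is attached as attribute `"seed"`.
#' @export
simulate_survey <- function(config, n = config$n, seed = config$seed) {
  assert_valid_config(config)
  if (!is.finite(config$nu))
    stopf("config$nu is not set; run calibrate_intercept() first")
  core <- simulate_core(config, n, seed)
  raw <- sweep(sweep(core$M, 2, config$mediators$raw_sd, `*`),
               2, config$mediators$raw_mean, `+`)
  raw <- round(raw)
  raw <- sweep(raw, 2, config$mediators$range_min, pmax)
  raw <- sweep(raw, 2, config$mediators$range_max, pmin)
  y <- with_seed(seed + 1L,
                 rbinom(n, 1, plogis(config$nu + core$lp_no_nu)))
  out <- data.frame(
    id = seq_len(n),
    hours_category = core$hours,
    sex = factor(ifelse(core$male == 1, "male", "female"),
                 levels = c("female", "male")),
    age_group = factor(ifelse(core$age_ge35 == 1, "35-64", "20-34"),
                       levels = c("20-34", "35-64")),
    experience_years = core$experience_years,
    night_shift = core$night_shift,
    job_stress_total = as.integer(raw[, "job_stress"]),
    sleep_total = as.integer(raw[, "sleep"]),
    depression_total = as.integer(raw[, "depression"]),
    fatigue_recovery = core$recovery,
    near_miss = y)
  attr(out, "seed") <- seed
  out
}

#' Read / write a survey file
#'
#' Comma-delimited, UTF-8, one header row, empty fields for missing values; a
#' leading `#` comment line records generator metadata (seed) when present.
#'
#' @param records survey data.frame (as from [simulate_survey()]).
#' @param path file path.
#' @return `read_survey` returns the records data.frame; `write_survey`
#'   returns `path` invisibly.
#' @export
write_survey <- function(records, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(attr(records, "seed")))
    writeLines(sprintf("# gsemmed synthetic survey; seed=%d; n=%d",
                       attr(records, "seed"), nrow(records)), con)
  write.csv(records, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  first <- readLines(path, n = 1L)
  rec <- read.csv(path, comment.char = "#", na.strings = "",
                  stringsAsFactors = FALSE, encoding = "UTF-8")
  if ("hours_category" %in% names(rec))
    rec$hours_category <- factor(rec$hours_category, levels = HOUR_LEVELS)
  if ("sex" %in% names(rec))
    rec$sex <- factor(rec$sex, levels = c("female", "male"))
  if ("age_group" %in% names(rec))
    rec$age_group <- factor(rec$age_group, levels = c("20-34", "35-64"))
  if (grepl("^# .*seed=", first)) {
    seed <- suppressWarnings(as.integer(sub(".*seed=(-?[0-9]+).*", "\\1", first)))
    if (!is.na(seed)) attr(rec, "seed") <- seed
  }
  rec
}

#' @export
print.gsem_config <- function(x, ...) {
  cat(sprintf("gsem_config: n = %d, seed = %d, psi = %g, nu = %s\n",
              x$n, x$seed, x$psi,
              if (is.finite(x$nu)) sprintf("%.4f", x$nu) else "<uncalibrated>"))
  cat(sprintf("  target prevalence: %.3f\n", x$target_prevalence))
  cat(sprintf("  p_hours: %s\n",
              paste(sprintf("%s=%.3f", names(x$p_hours), x$p_hours),
                    collapse = ", ")))
  invisible(x)
}
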