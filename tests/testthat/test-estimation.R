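test_that("mediator standardization follows the sample-SD z-score convention", {
  df <- data.frame(job_stress_total = c(1, 2, 3))
  out <- standardize_mediators(df)
  expect_equal(out$records$job_stress_total, c(-1, 0, 1))
  expect_equal(out$scaling$mean, 2)
  expect_equal(out$scaling$sd, 1)
  # idempotence on already-standardized columns
  again <- standardize_mediators(out$records)
  expect_equal(again$records$job_stress_total, out$records$job_stress_total,
               tolerance = 1e-12)
  expect_error(standardize_mediators(data.frame(sleep_total = rep(2, 5))),
               "distinct")
})

test_that("the logistic sub-fit equals an independent IRLS oracle to 1e-8", {
  d <- simulate_survey(cached_config(), n = 3000, seed = 21)
  fit <- fit_composite(d)
  # reconstruct the outcome design independently of the package internals
  z <- function(x) (x - mean(x)) / sd(x)
  X <- cbind(1,
             d$hours_category == "41-50",
             d$hours_category == "51-60",
             d$hours_category == ">=61",
             z(d$job_stress_total), z(d$sleep_total), z(d$depression_total),
             d$sex == "male",
             d$age_group == "35-64")
  beta <- irls_logistic(X * 1, d$near_miss)
  got <- setNames(fit$estimate, paste0(fit$source, "->", fit$target))
  expect_equal(unname(got[c("hours41_50->near_miss", "hours51_60->near_miss",
                            "hours61plus->near_miss")]),
               beta[2:4], tolerance = 1e-8)
  expect_equal(unname(got[c("job_stress->fatigue", "sleep->fatigue",
                            "depression->fatigue")]),
               beta[5:7], tolerance = 1e-8)   # loading fixed at 1.00
  expect_equal(unname(got[c("male->near_miss", "age_ge35->near_miss")]),
               beta[8:9], tolerance = 1e-8)
})

test_that("the composite joint likelihood factorizes and matches glm/lm oracles", {
  d <- cached_small_sim()
  fit <- fit_composite(d)
  meta <- attr(fit, "meta")
  expect_identical(meta$loglik, meta$loglik_mediators + meta$loglik_outcome)
  # independent equation likelihoods via the formula interfaces
  z <- function(x) (x - mean(x)) / sd(x)
  dd <- transform(d, js = z(job_stress_total), sl = z(sleep_total),
                  dp = z(depression_total))
  ll_med <- as.numeric(logLik(lm(js ~ hours_category, dd))) +
    as.numeric(logLik(lm(sl ~ hours_category, dd))) +
    as.numeric(logLik(lm(dp ~ hours_category, dd)))
  ll_out <- as.numeric(logLik(glm(near_miss ~ hours_category + js + sl + dp +
                                    sex + age_group,
                                  binomial(), dd)))
  expect_equal(meta$loglik_mediators, ll_med, tolerance = 1e-6)
  expect_equal(meta$loglik_outcome, ll_out, tolerance = 1e-6)
})

test_that("standardized estimates are invariant to rescaling a mediator column", {
  d <- cached_small_sim()
  f1 <- fit_composite(d)
  d2 <- d
  d2$job_stress_total <- d2$job_stress_total * 3.7
  f2 <- fit_composite(d2)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
})

test_that("a permuted outcome yields null exposure and mediator coefficients", {
  d <- cached_small_sim()
  perm <- order(sin(seq_len(nrow(d)) * 12.9898))   # fixed pseudo-permutation
  d$near_miss <- d$near_miss[perm]
  fit <- fit_composite(d)
  into_outcome <- (fit$target == "near_miss" & !fit$fixed) |
    fit$target == "fatigue"
  zscores <- abs(fit$estimate[into_outcome] / fit$se[into_outcome])
  expect_true(all(zscores < 3.5))
})

test_that("odds ratios attach only to estimated outcome-equation edges", {
  tab <- coefficients_to_or(published_coef_table())
  key <- paste0(tab$source, "->", tab$target)
  expect_equal(round(tab$or[key == "hours41_50->near_miss"], 2), 1.11)
  expect_equal(round(tab$or[key == "age_ge35->near_miss"], 2), 0.85)
  expect_true(is.na(tab$or[key == "fatigue->near_miss"]))   # fixed loading
  expect_true(all(is.na(tab$or[tab$target != "near_miss"])))
  expect_equal(coefficients_to_or(coef_table("a", "near_miss", 0))$or, 1)
})

test_that("the latent-disturbance fit with psi = 0 reduces to the composite fit", {
  d <- cached_small_sim()
  fc <- fit_composite(d)
  fl <- fit_latent(d, default_model(mode = "latent_disturbance"), psi = 0)
  expect_equal(attr(fl, "meta")$loglik, attr(fc, "meta")$loglik,
               tolerance = 1e-6)
  expect_equal(fl$estimate, fc$estimate, tolerance = 1e-6)
})

test_that("estimates are insensitive to the quadrature node count", {
  d <- cached_small_sim()
  f21 <- fit_latent(d, default_model(mode = "latent_disturbance"),
                    quadrature_nodes = 21)
  f41 <- fit_latent(d, default_model(mode = "latent_disturbance"),
                    quadrature_nodes = 41)
  expect_lt(max(abs(f21$estimate - f41$estimate)), 1e-4)
  expect_lt(abs(attr(f21, "meta")$psi - attr(f41, "meta")$psi), 1e-4)
})

test_that("the marginal-likelihood gradient matches numerical differentiation", {
  set.seed(4)
  n <- 400
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  y <- rbinom(n, 1, plogis(drop(X %*% c(0.2, 0.5, -0.3))))
  gh <- pracma::gaussHermite(15)
  zj <- sqrt(2) * gh$x
  wj <- gh$w / sqrt(pi)
  f <- gsemmed:::gh_marginal_nll(X, y, zj, wj)
  g <- gsemmed:::gh_marginal_grad(X, y, zj, wj)
  par <- c(0.1, 0.4, -0.2, 0.7)
  num <- vapply(seq_along(par), function(i) {
    h <- 1e-6
    e <- par
    e[i] <- e[i] + h
    (f(e) - f(par)) / h
  }, 0)
  expect_equal(g(par), num, tolerance = 1e-4)
})
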