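test_that("default configuration carries the published margins and paths", {
  cfg <- cached_config()
  expect_equal(round(unname(cfg$p_hours), 3), c(0.340, 0.446, 0.114, 0.099))
  expect_equal(sum(cfg$p_hours), 1)
  expect_equal(unname(cfg$b), c(0.397, 0.239, -0.021))
  expect_equal(unname(cfg$a["hours51_60", ]), c(0.556, 0.168, 0.142))
  expect_equal(unname(cfg$d), c(0.100, 0.087, 0.016))
  expect_equal(round(cfg$p_female, 3), 0.767)
  expect_equal(round(unname(cfg$p_experience), 3), c(0.190, 0.323, 0.487))
  expect_length(validate_config(cfg), 0)
  expect_true(is.finite(cfg$nu))
})

test_that("configuration validation rejects broken inputs", {
  cfg <- cached_config()
  bad <- cfg
  bad$p_hours <- c(bad$p_hours[-4], 0.2)
  expect_match(paste(validate_config(bad), collapse = "; "), "sum to 1")
  bad <- cfg
  bad$psi <- -1
  expect_match(paste(validate_config(bad), collapse = "; "), "psi")
  bad <- cfg
  bad$residual_corr <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_match(paste(validate_config(bad), collapse = "; "),
               "positive semi-definite")
  expect_error(simulate_survey(bad), "invalid generator config")
})

test_that("intercept calibration matches the closed form for a null model", {
  cfg <- default_config(calibrate = FALSE)
  cfg$a[] <- 0
  cfg$b[] <- 0
  cfg$d[] <- 0
  cfg$gamma[] <- 0
  expect_equal(calibrate_intercept(cfg, 0.5), 0, tolerance = 1e-6)
  expect_equal(calibrate_intercept(cfg, 0.25), qlogis(0.25), tolerance = 1e-6)
  expect_error(calibrate_intercept(cfg, 1.5), "target_prevalence")
})

test_that("re-simulation under the calibrated default hits the target prevalence", {
  d <- cached_big_sim()
  expect_lt(abs(mean(d$near_miss) - 0.491), 0.004)
})

test_that("identical seed and config give byte-identical survey files", {
  cfg <- cached_config()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(simulate_survey(cfg, n = 400, seed = 11), f1)
  write_survey(simulate_survey(cfg, n = 400, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  r <- read_survey(f1)
  expect_equal(attr(r, "seed"), 11)
  expect_equal(nrow(r), 400)
  expect_s3_class(r$hours_category, "factor")
})

test_that("margins and instrument moments match the configuration at large n", {
  cfg <- cached_config()
  d <- cached_big_sim()
  n <- nrow(d)
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  for (lv in levels(d$hours_category)) {
    p <- cfg$p_hours[[lv]]
    expect_lt(abs(mean(d$hours_category == lv) - p), se3(p))
  }
  expect_lt(abs(mean(d$sex == "female") - cfg$p_female), se3(cfg$p_female))
  expect_lt(abs(mean(d$age_group == "35-64") - cfg$p_age_ge35),
            se3(cfg$p_age_ge35))
  expect_lt(abs(mean(d$night_shift) - cfg$p_nightshift),
            se3(cfg$p_nightshift))
  expect_lt(abs(mean(d$experience_years <= 3) - cfg$p_experience[["le3"]]),
            se3(cfg$p_experience[["le3"]]))
  # job-stress raw moments: clipping is negligible 3.5+ SD from the bounds
  expect_lt(abs(mean(d$job_stress_total) - 44.0), 0.1)
  expect_lt(abs(sd(d$job_stress_total) - 6.3), 0.1)
  expect_lt(abs(mean(d$sleep_total) - 5.8), 0.15)
  # scores stay within the legal instrument ranges
  expect_true(all(d$job_stress_total >= 17 & d$job_stress_total <= 68))
  expect_true(all(d$sleep_total >= 0 & d$sleep_total <= 21))
  expect_true(all(d$depression_total >= 0 & d$depression_total <= 60))
})

test_that("a fully null generator leaves the outcome independent of hours", {
  cfg <- default_config(calibrate = FALSE)
  cfg$a[] <- 0
  cfg$b[] <- 0
  cfg$d[] <- 0
  cfg$gamma[] <- 0
  cfg$nu <- 0
  d <- simulate_survey(cfg, n = 50000, seed = 31)
  expect_lt(abs(mean(d$near_miss) - 0.5), 0.01)
  p <- chisq.test(table(d$hours_category, d$near_miss))$p.value
  expect_gt(p, 0.001)
})

test_that("a stronger stress path raises mean stress in the exposed stratum", {
  cfg <- cached_config()
  cfg2 <- cfg
  cfg2$a["hours61plus", "job_stress"] <- 1.2
  d1 <- simulate_survey(cfg, n = 50000, seed = 17)
  d2 <- simulate_survey(cfg2, n = 50000, seed = 17)
  m1 <- mean(d1$job_stress_total[d1$hours_category == ">=61"])
  m2 <- mean(d2$job_stress_total[d2$hours_category == ">=61"])
  expect_gt(m2, m1 + 1)     # +0.51 SD on a 6.3-point scale
})
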