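test_that("published coefficients reproduce the published effect table", {
  eff <- decompose_effects(published_coef_table(),
                           enumerate_paths(default_model()))
  # direct effects
  expect_equal(round(effect_or(eff, "hours41_50", "direct"), 2), 1.11)
  expect_equal(round(effect_or(eff, "hours51_60", "direct"), 2), 1.09)
  expect_equal(round(effect_or(eff, "hours61plus", "direct"), 2), 1.02)
  # indirect via job stress
  expect_equal(round(effect_or(eff, "hours41_50", "indirect", "job_stress"), 2),
               1.12)
  expect_equal(round(effect_or(eff, "hours51_60", "indirect", "job_stress"), 2),
               1.25)
  # totals
  expect_equal(round(effect_or(eff, "hours41_50", "total"), 2), 1.26)
  expect_equal(round(effect_or(eff, "hours51_60", "total"), 2), 1.41)
  expect_equal(round(effect_or(eff, "hours61plus", "total"), 2), 1.41)
  # reference level is all ones
  expect_true(all(eff$or[eff$level == "hours35_40"] == 1))
})

test_that("decomposition is additive on the log scale and matches a brute-force oracle", {
  skip_if_not_installed("igraph")
  for (s in 11:16) {
    m <- random_model(s)
    tab <- random_coef_table(m, s + 100)
    paths <- enumerate_paths(m)
    eff <- decompose_effects(tab, paths)
    est <- setNames(tab$estimate, paste0(tab$source, "->", tab$target))
    for (lv in unique(paths$level)) {
      rows <- eff[eff$level == lv, ]
      total <- rows$log_effect[rows$effect_type == "total"]
      direct <- sum(rows$log_effect[rows$effect_type == "direct"])
      indirect <- sum(rows$log_effect[rows$effect_type == "indirect"])
      expect_identical(total, direct + indirect)
      # independent oracle: sum of edge-coefficient products over igraph's
      # exhaustive path list
      oracle <- sum(vapply(strsplit(igraph_paths(m, lv, "y"), " -> ",
                                    fixed = TRUE), function(nd)
        prod(est[paste0(nd[-length(nd)], "->", nd[-1])]), 0))
      expect_equal(total, oracle, tolerance = 1e-12)
      # OR multiplicativity
      expect_equal(rows$or[rows$effect_type == "total"],
                   prod(rows$or[rows$effect_type != "total"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("mediator chains contribute their full path product to the first mediator", {
  m <- add_model_edges(default_model(), "job_stress", "sleep")
  tab <- published_coef_table()
  tab <- rbind(tab, coef_table("job_stress", "sleep", 0.3))
  class(tab) <- c("gsem_coefs", "data.frame")
  eff <- decompose_effects(tab, enumerate_paths(m))
  base <- decompose_effects(published_coef_table(),
                            enumerate_paths(default_model()))
  for (lv in c("hours41_50", "hours51_60", "hours61plus")) {
    a_stress <- tab$estimate[tab$source == lv & tab$target == "job_stress"]
    extra <- a_stress * 0.3 * 0.239 * 1.00   # X -> stress -> sleep -> fatigue -> Y
    expect_equal(
      log(effect_or(eff, lv, "indirect", "job_stress")),
      log(effect_or(base, lv, "indirect", "job_stress")) + extra,
      tolerance = 1e-12)
  }
  contrib <- attr(eff, "path_contributions")
  expect_true("hours41_50 -> job_stress -> sleep -> fatigue -> near_miss"
              %in% contrib$path)
})

test_that("zero coefficients give unit odds ratios everywhere", {
  m <- default_model()
  tab <- coef_table(m$edges$from, m$edges$to, 0)
  eff <- decompose_effects(tab, enumerate_paths(m))
  expect_true(all(eff$or == 1))
})

test_that("a missing path edge raises rather than silently dropping", {
  tab <- published_coef_table()
  tab <- tab[!(tab$source == "sleep" & tab$target == "fatigue"), ]
  expect_error(decompose_effects(tab, enumerate_paths(default_model())),
               "absent from the coefficient table")
})

test_that("path enumeration order does not change the sums", {
  m <- add_model_edges(default_model(), "job_stress", "sleep")
  paths <- enumerate_paths(m)
  set.seed(5)
  shuffled <- paths[sample(nrow(paths)), ]
  e1 <- decompose_effects(published_coef_table_ext(), paths)
  e2 <- decompose_effects(published_coef_table_ext(), shuffled)
  key <- function(e) paste(e$level, e$effect_type, e$first_mediator)
  expect_equal(e1$log_effect[order(key(e1))], e2$log_effect[order(key(e2))])
})

test_that("formatted effect tables render and round-trip at two decimals", {
  eff <- decompose_effects(published_coef_table(),
                           enumerate_paths(default_model()))
  ft <- format_effect_table(eff)
  expect_equal(ft$level, c("35-40", "41-50", "51-60", ">=61"))
  expect_equal(ft$direct[1], "1.00 (reference)")
  expect_equal(ft$indirect_job_stress[2], "1.12")
  # parse(format(x)) == round(x, 2)
  parsed <- as.numeric(sub(" .*", "", ft$total[-1]))
  truth <- vapply(c("hours41_50", "hours51_60", "hours61plus"),
                  effect_or, 0, eff = eff, type = "total")
  expect_equal(parsed, round(unname(truth), 2))
  # CI columns appear when CIs are supplied
  cis <- data.frame(quantity = "hours41_50|total", low = 0.1, high = 0.3)
  ft2 <- format_effect_table(eff, cis = cis)
  expect_match(ft2$total[2], "^1\\.26 \\(1\\.11, 1\\.35\\)$")
})
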