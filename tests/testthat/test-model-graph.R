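test_that("default model has the expected graph structure and constraint", {
  m <- default_model()
  expect_equal(nrow(m$nodes), 10)
  expect_equal(nrow(m$edges), 18)
  expect_equal(m$constraints, c("fatigue->near_miss" = 1.00))
  expect_length(validate_model(m), 0)
  expect_false(m$reference_level %in% m$nodes$name)
})

test_that("validation reports each structural violation as a message", {
  m <- default_model()
  expect_match(paste(validate_model(
    add_model_edges(m, "near_miss", "job_stress")), collapse = "; "),
    "cycle")
  m_noscale <- m
  m_noscale$constraints <- setNames(numeric(0), character(0))
  expect_match(paste(validate_model(m_noscale), collapse = "; "),
               "unconstrained latent scale")
  expect_match(paste(validate_model(
    add_model_edges(m, "sleep", "near_miss")), collapse = "; "),
    "mediator -> outcome", fixed = TRUE)
  m_ref <- m
  m_ref$reference_level <- "hours41_50"
  expect_match(paste(validate_model(m_ref), collapse = "; "),
               "reference_level")
  m_2lat <- m
  m_2lat$nodes$role[m_2lat$nodes$name == "sleep"] <- "latent"
  expect_match(paste(validate_model(m_2lat), collapse = "; "),
               "exactly 1 latent")
  expect_error(enumerate_paths(add_model_edges(m, "near_miss", "job_stress")),
               "invalid model")
})

test_that("each exposure level has one direct and one path per mediator", {
  p <- enumerate_paths(default_model())
  expect_equal(as.integer(table(p$level)), rep(4L, 3))
  for (lv in unique(p$level)) {
    labs <- sort(p$first_mediator[p$level == lv])
    expect_equal(labs, sort(c("direct", "job_stress", "sleep", "depression")))
  }
  expect_true(all(vapply(p$nodes, function(nd)
    nd[length(nd)] == "near_miss", TRUE)))
})

test_that("mediator chains are grouped under the first mediator on the path", {
  m <- add_model_edges(default_model(),
                       c("job_stress", "job_stress"),
                       c("sleep", "depression"))
  expect_length(validate_model(m), 0)
  p <- enumerate_paths(m)
  expect_equal(as.integer(table(p$level)), rep(6L, 3))
  chain <- p[p$path ==
    "hours41_50 -> job_stress -> sleep -> fatigue -> near_miss", ]
  expect_equal(nrow(chain), 1)
  expect_equal(chain$first_mediator, "job_stress")
  expect_equal(sum(p$first_mediator == "job_stress" & p$level == "hours41_50"),
               3)
})

test_that("enumeration matches exhaustive igraph search on random DAGs", {
  skip_if_not_installed("igraph")
  for (s in 1:8) {
    m <- random_model(s)
    p <- enumerate_paths(m)
    for (x in m$nodes$name[m$nodes$role == "exposure_level"]) {
      expect_equal(sort(p$path[p$level == x]), igraph_paths(m, x, "y"),
                   info = sprintf("seed %d, exposure %s", s, x))
    }
  }
})

test_that("enumeration is deterministic with lexicographic path order", {
  m <- add_model_edges(default_model(), "job_stress", "sleep")
  p1 <- enumerate_paths(m)
  p2 <- enumerate_paths(m)
  expect_identical(p1$path, p2$path)
  for (lv in unique(p1$level))
    expect_equal(p1$path[p1$level == lv], sort(p1$path[p1$level == lv]))
})

test_that("model configs round-trip through YAML and JSON; DOT marks the latent", {
  m <- default_model()
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(m, f)
    m2 <- read_model_config(f)
    expect_equal(m2$nodes, m$nodes)
    expect_equal(m2$edges, m$edges)
    expect_equal(m2$constraints, m$constraints)
    expect_equal(m2$mode, m$mode)
    expect_equal(m2$reference_level, m$reference_level)
    expect_length(validate_model(m2), 0)
  }
  dot <- model_to_dot(m)
  expect_match(dot, "\"fatigue\" \\[shape=ellipse\\]")
  expect_match(dot, "fixed 1.00", fixed = TRUE)
})
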