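# Independent oracles and shared fixtures. Everything here is deliberately
# written without reusing the package's own code paths, so tests compare two
# independent routes to the same quantity.

# Hand-rolled IRLS for logistic regression: weighted least-squares updates
# until the coefficient change is below tol.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    new <- qr.solve(X * sqrt(w), z * sqrt(w))
    if (max(abs(new - beta)) < tol) {
      beta <- new
      break
    }
    beta <- new
  }
  beta
}

# Exhaustive simple-path enumeration via igraph (independent of the
# package's recursive walker).
igraph_paths <- function(model, from, to) {
  g <- igraph::graph_from_data_frame(model$edges,
                                     vertices = model$nodes$name)
  ps <- igraph::all_simple_paths(g, from = from, to = to, mode = "out")
  sort(vapply(ps, function(p) paste(names(p), collapse = " -> "), ""))
}

# Random valid model graphs: variable numbers of exposure dummies, mediators
# and covariates, plus random forward mediator -> mediator edges (acyclic by
# construction).
random_model <- function(seed) {
  set.seed(seed)
  nE <- sample(1:3, 1)
  nM <- sample(2:4, 1)
  nC <- sample(0:2, 1)
  ex <- paste0("x", seq_len(nE))
  me <- paste0("m", seq_len(nM))
  cv <- if (nC) paste0("c", seq_len(nC)) else character(0)
  nodes <- data.frame(
    name = c(ex, me, "lat", "y", cv),
    role = c(rep("exposure_level", nE), rep("mediator", nM),
             "latent", "outcome", rep("covariate", nC)))
  edges <- rbind(
    expand.grid(from = ex, to = me, stringsAsFactors = FALSE),
    data.frame(from = ex, to = "y"),
    data.frame(from = me, to = "lat"),
    data.frame(from = "lat", to = "y"),
    if (nC) data.frame(from = cv, to = "y"))
  # forward mediator -> mediator edges keep the graph acyclic
  for (i in seq_len(nM - 1))
    for (j in seq((i + 1), nM))
      if (runif(1) < 0.4)
        edges <- rbind(edges, data.frame(from = me[i], to = me[j]))
  gsem_model(nodes, edges, constraints = c("lat->y" = 1),
             reference_level = "x0")
}

random_coef_table <- function(model, seed) {
  set.seed(seed)
  est <- round(rnorm(nrow(model$edges), sd = 0.4), 3)
  keys <- paste0(model$edges$from, "->", model$edges$to)
  fixed <- keys %in% names(model$constraints)
  est[fixed] <- model$constraints[keys[fixed]]
  coef_table(model$edges$from, model$edges$to, est, fixed = fixed)
}

# The published point estimates as a coefficient table: inputs for the
# worked-example decomposition.
published_coef_table <- function() {
  src <- c("hours41_50", "hours51_60", "hours61plus")
  coef_table(
    source = c(src, src, src, src,
               "job_stress", "sleep", "depression", "fatigue",
               "male", "age_ge35"),
    target = c(rep("near_miss", 3), rep("job_stress", 3), rep("sleep", 3),
               rep("depression", 3), rep("fatigue", 3),
               "near_miss", "near_miss", "near_miss"),
    estimate = c(0.100, 0.087, 0.016,
                 0.290, 0.556, 0.690,
                 0.056, 0.168, 0.263,
                 0.007, 0.142, 0.362,
                 0.397, 0.239, -0.021,
                 1.00,
                 0.070, -0.157),
    fixed = c(rep(FALSE, 15), TRUE, FALSE, FALSE))
}

# Published table plus the sensitivity-variant stress -> sleep path.
published_coef_table_ext <- function() {
  tab <- rbind(published_coef_table(), coef_table("job_stress", "sleep", 0.3))
  class(tab) <- c("gsem_coefs", "data.frame")
  tab
}

effect_or <- function(eff, level, type, mediator = NA) {
  sel <- eff$level == level & eff$effect_type == type &
    (is.na(mediator) | (!is.na(eff$first_mediator) &
                        eff$first_mediator == mediator))
  eff$or[sel][1]
}

# Shared fixtures, built once per test session.
.cache <- new.env(parent = emptyenv())

cached_config <- function() {
  if (is.null(.cache$cfg)) .cache$cfg <- default_config()
  .cache$cfg
}

# One large default-configuration simulation reused by the margin, moment,
# descriptive and parameter-recovery checks.
cached_big_sim <- function() {
  if (is.null(.cache$big))
    .cache$big <- simulate_survey(cached_config(), n = 200000, seed = 104729)
  .cache$big
}

cached_small_sim <- function() {
  if (is.null(.cache$small))
    .cache$small <- simulate_survey(cached_config(), n = 1490, seed = 2027)
  .cache$small
}
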