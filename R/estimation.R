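# GSEM estimation. In composite mode the latent fatigue variable is a
# deterministic weighted sum of the standardized mediators, so the joint
# likelihood factorizes into one Gaussian linear equation per mediator plus a
# single logistic outcome equation; because the fatigue -> outcome loading is
# fixed, the mediator coefficients of the logistic fit are (loading x) the
# mediator -> fatigue loadings. In latent-disturbance mode fatigue carries
# its own normal error which is integrated out of the outcome likelihood by
# Gauss-Hermite quadrature.

#' Standardize mediator totals
#'
#' Replaces each mediator total by its z-score, `(x - mean) / sd`, with the
#' sample standard deviation (denominator n - 1). Dummies and the binary
#' outcome are untouched. Path coefficients involving mediators are reported
#' on this standardized scale.
#'
#' @param records survey data.frame.
#' @param columns mediator columns to standardize; defaults to the
#'   questionnaire totals present in `records`.
#' @return list with `records` (transformed data.frame) and `scaling`
#'   (data.frame of column, mean, sd for the inverse mapping).
#' @export
standardize_mediators <- function(records, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(MEDIATORS$column, names(records))
  if (!length(columns)) stopf("no mediator columns found")
  scaling <- data.frame(column = columns, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    x <- records[[columns[i]]]
    if (length(unique(x[!is.na(x)])) < 2)
      stopf("mediator '%s' has fewer than 2 distinct values", columns[i])
    m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (s == 0) stopf("mediator '%s' has zero variance", columns[i])
    records[[columns[i]]] <- (x - m) / s
    scaling$mean[i] <- m; scaling$sd[i] <- s
  }
  list(records = records, scaling = scaling)
}

# Map a model node to a numeric column derived from the survey records.
node_values <- function(node, role, records, model) {
  if (role == "exposure_level") {
    lab <- model$level_map[[node]] %||% node
    return(as.numeric(as.character(records$hours_category) == lab))
  }
  if (node %in% names(records)) return(as.numeric(records[[node]]))
  alt <- paste0(node, "_total")
  if (alt %in% names(records)) return(as.numeric(records[[alt]]))
  if (node == "male" && "sex" %in% names(records))
    return(as.numeric(as.character(records$sex) == "male"))
  if (node == "age_ge35") {
    if ("age_group" %in% names(records))
      return(as.numeric(as.character(records$age_group) == "35-64"))
    if ("age" %in% names(records))
      return(as.numeric(records$age >= 35))
  }
  stopf("no data column found for model node '%s'", node)
}

canonical_edge_order <- function(model) {
  exposures <- nodes_of_role(model, "exposure_level")
  mediators <- nodes_of_role(model, "mediator")
  covariates <- nodes_of_role(model, "covariate")
  latent <- nodes_of_role(model, "latent")
  outcome <- nodes_of_role(model, "outcome")
  has <- function(f, t) any(model$edges$from == f & model$edges$to == t)
  keys <- character(0)
  add <- function(f, t) if (has(f, t)) keys <<- c(keys, edge_key(f, t))
  for (x in exposures) add(x, outcome)
  for (m in mediators)
    for (p in c(exposures, covariates, mediators)) add(p, m)
  for (m in mediators) add(m, latent)
  add(latent, outcome)
  for (cv in covariates) add(cv, outcome)
  all_keys <- edge_key(model$edges$from, model$edges$to)
  c(keys, setdiff(all_keys, keys))
}

# Precompute everything needed to (re)fit the equations on arbitrary row
# subsets: numeric node matrix after listwise deletion, per-equation
# regressor lists, and the canonical edge order.
build_fit_context <- function(records, model) {
  assert_valid_model(model)
  outcome <- nodes_of_role(model, "outcome")
  latent <- nodes_of_role(model, "latent")
  mediators <- nodes_of_role(model, "mediator")
  observed <- setdiff(model$nodes$name, latent)
  cols <- lapply(observed, function(nd)
    node_values(nd, node_role(model, nd), records, model))
  D <- do.call(cbind, cols)
  colnames(D) <- observed
  keep <- complete.cases(D)
  # full-time eligibility is implicit: rows with an unknown hours category
  # produce NA dummies and are dropped here
  D <- D[keep, , drop = FALSE]
  if (!nrow(D)) stopf("no complete records for the model variables")
  topo <- topo_sort(model$nodes$name, model$edges)
  med_order <- topo[topo %in% mediators]
  lat_parents <- parents_of(model, latent)
  if (!all(lat_parents %in% mediators))
    stopf("latent parents must all be mediators")
  out_direct <- setdiff(parents_of(model, outcome), latent)
  key <- edge_key(model$edges$from, model$edges$to)
  loading <- model$constraints[[edge_key(latent, outcome)]]
  list(model = model, data = D, n = nrow(D), n_dropped = sum(!keep),
       y = D[, outcome], outcome = outcome, latent = latent,
       mediators = med_order, lat_parents = sort(lat_parents),
       med_parents = setNames(lapply(med_order, parents_of, model = model),
                              med_order),
       out_direct = out_direct, loading = loading,
       edge_order = canonical_edge_order(model))
}

binom_loglik <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

gaussian_ml_loglik <- function(r) {
  n <- length(r); s2 <- sum(r^2) / n
  -n / 2 * (log(2 * pi) + log(s2) + 1)
}

# Fit all equations on the rows `idx` of a fit context. se = FALSE is the
# fast path used by the bootstrap (no vcov, no formula interface).
fit_equations <- function(ctx, idx = seq_len(ctx$n), se = TRUE, start = NULL) {
  D <- ctx$data[idx, , drop = FALSE]
  n <- nrow(D)
  scaling <- data.frame(node = ctx$mediators, mean = NA_real_, sd = NA_real_)
  for (k in seq_along(ctx$mediators)) {
    m <- ctx$mediators[k]
    mu <- mean(D[, m]); s <- sd(D[, m])
    if (!is.finite(s) || s == 0)
      stopf("mediator '%s' has zero variance in this sample", m)
    D[, m] <- (D[, m] - mu) / s
    scaling$mean[k] <- mu; scaling$sd[k] <- s
  }
  est <- se_ <- numeric(0)
  intercepts <- resid_var <- numeric(0)
  loglik_med <- 0
  for (m in ctx$mediators) {
    pa <- ctx$med_parents[[m]]
    X <- cbind(`(Intercept)` = 1, D[, pa, drop = FALSE])
    f <- lm.fit(X, D[, m])
    cf <- setNames(f$coefficients, colnames(X))
    if (any(!is.finite(cf)))
      stopf("rank-deficient design in the '%s' equation", m)
    est <- c(est, setNames(cf[pa], edge_key(pa, m)))
    intercepts[m] <- cf[["(Intercept)"]]
    r <- f$residuals
    p <- f$rank
    resid_var[m] <- sum(r^2) / n                       # ML variance
    loglik_med <- loglik_med + gaussian_ml_loglik(r)
    if (se) {
      sigma2 <- sum(r^2) / (n - p)
      V <- chol2inv(f$qr$qr[seq_len(p), seq_len(p), drop = FALSE]) * sigma2
      se_ <- c(se_, setNames(sqrt(diag(V))[match(pa, colnames(X))],
                             edge_key(pa, m)))
    }
  }
  Xo <- cbind(`(Intercept)` = 1,
              D[, c(ctx$out_direct, ctx$lat_parents), drop = FALSE])
  gf <- suppressWarnings(
    glm.fit(Xo, D[, ctx$outcome], family = binomial(), start = start,
            control = list(epsilon = 1e-8, maxit = 100)))
  cf <- setNames(gf$coefficients, colnames(Xo))
  converged <- isTRUE(gf$converged)
  separated <- any(abs(cf[-1]) > 30) || any(!is.finite(cf))
  if (!converged) stopf("logistic outcome equation did not converge")
  if (separated)
    stopf("perfect separation detected in the logistic outcome equation")
  est <- c(est,
           setNames(cf[ctx$out_direct], edge_key(ctx$out_direct, ctx$outcome)),
           setNames(cf[ctx$lat_parents] / ctx$loading,
                    edge_key(ctx$lat_parents, ctx$latent)))
  intercepts[ctx$outcome] <- cf[["(Intercept)"]]
  loglik_out <- binom_loglik(D[, ctx$outcome], gf$fitted.values)
  if (se) {
    p <- gf$rank
    Vg <- chol2inv(gf$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    seg <- setNames(sqrt(diag(Vg)), colnames(Xo))
    se_ <- c(se_,
             setNames(seg[ctx$out_direct],
                      edge_key(ctx$out_direct, ctx$outcome)),
             setNames(seg[ctx$lat_parents] / abs(ctx$loading),
                      edge_key(ctx$lat_parents, ctx$latent)))
  }
  # fixed edges enter the coefficient vector at their constraint value
  est <- c(est, ctx$model$constraints)
  list(est = est, se = se_, intercepts = intercepts, resid_var = resid_var,
       loglik = loglik_med + loglik_out, loglik_mediators = loglik_med,
       loglik_outcome = loglik_out, scaling = scaling, n = n,
       outcome_design = Xo, outcome_y = D[, ctx$outcome],
       outcome_coef = cf)
}

new_coef_table <- function(ctx, eq, meta_extra = list()) {
  keys <- ctx$edge_order
  parts <- strsplit(keys, "->", fixed = TRUE)
  tab <- data.frame(
    source = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 2L),
    estimate = unname(eq$est[keys]),
    se = unname(if (length(eq$se)) eq$se[keys] else rep(NA_real_, length(keys))),
    fixed = keys %in% names(ctx$model$constraints),
    stringsAsFactors = FALSE)
  meta <- c(list(mode = ctx$model$mode, n = eq$n, n_dropped = ctx$n_dropped,
                 loglik = eq$loglik, loglik_mediators = eq$loglik_mediators,
                 loglik_outcome = eq$loglik_outcome,
                 intercepts = eq$intercepts, resid_var = eq$resid_var,
                 scaling = eq$scaling, converged = TRUE,
                 model = ctx$model),
            meta_extra)
  attr(tab, "meta") <- meta
  class(tab) <- c("gsem_coefs", "data.frame")
  tab
}

#' Fit the GSEM in composite mode
#'
#' Fits one Gaussian linear regression per mediator (standardized mediator on
#' its graph parents) and one logistic regression of the outcome on the
#' exposure dummies, covariates and standardized mediators. With the fatigue
#' loading fixed (at 1.00 by default) the mediator coefficients of the
#' logistic equation are exactly `loading x` the mediator -> fatigue
#' loadings, which is how they are reported. The joint log-likelihood is the
#' sum of the equation log-likelihoods (it factorizes because the composite
#' has no disturbance); both are stored in the fit metadata.
#'
#' Listwise deletion is applied over all model variables. Perfect separation
#' and non-convergence of the logistic solver raise errors rather than
#' returning silently wrong estimates.
#'
#' @param records survey data.frame.
#' @param model a valid `gsem_model` with `mode = "composite"`.
#' @return a `gsem_coefs` data.frame (columns `source`, `target`, `estimate`,
#'   `se`, `fixed`) in the canonical report order, with fit metadata in
#'   `attr(, "meta")` (mode, n, log-likelihoods, intercepts, residual
#'   variances, mediator scaling, the model).
#' @export
fit_composite <- function(records, model = default_model()) {
  if (model$mode != "composite")
    stopf("fit_composite requires mode = 'composite'")
  ctx <- build_fit_context(records, model)
  eq <- fit_equations(ctx, se = TRUE)
  new_coef_table(ctx, eq)
}

gh_marginal_nll <- function(X, y, zj, wj, s_fixed = NULL) {
  q <- 2 * y - 1
  function(par) {
    p <- ncol(X)
    beta <- par[seq_len(p)]
    s <- if (is.null(s_fixed)) par[p + 1L] else s_fixed
    eta <- drop(X %*% beta) * q
    A <- outer(eta, rep(1, length(zj))) + outer(q * s, zj)
    P <- plogis(A)
    L <- drop(P %*% wj)
    -sum(log(pmax(L, 1e-300)))
  }
}

gh_marginal_grad <- function(X, y, zj, wj, s_fixed = NULL) {
  q <- 2 * y - 1
  function(par) {
    p <- ncol(X)
    beta <- par[seq_len(p)]
    s <- if (is.null(s_fixed)) par[p + 1L] else s_fixed
    eta <- drop(X %*% beta) * q
    A <- outer(eta, rep(1, length(zj))) + outer(q * s, zj)
    P <- plogis(A)
    W <- P * (1 - P)
    L <- pmax(drop(P %*% wj), 1e-300)
    gb <- -drop(crossprod(X, q * drop(W %*% wj) / L))
    if (is.null(s_fixed)) c(gb, -sum(q * drop(W %*% (wj * zj)) / L))
    else gb
  }
}

# Damped Newton maximization of the GH marginal outcome likelihood in beta at
# fixed disturbance scale s (analytic gradient and Hessian).
gh_profile_fit <- function(X, y, zj, wj, s, beta0) {
  q <- 2 * y - 1
  m <- length(zj)
  beta <- beta0
  nll_at <- function(b) {
    A <- outer(drop(X %*% b) * q, rep(1, m)) + outer(q * s, zj)
    -sum(log(pmax(drop(plogis(A) %*% wj), 1e-300)))
  }
  nll_cur <- nll_at(beta)
  converged <- FALSE
  for (it in seq_len(100L)) {
    A <- outer(drop(X %*% beta) * q, rep(1, m)) + outer(q * s, zj)
    P <- plogis(A)
    W <- P * (1 - P)
    L <- pmax(drop(P %*% wj), 1e-300)
    g1 <- drop(W %*% wj) / L
    grad <- drop(crossprod(X, q * g1))                 # of loglik
    curv <- drop((W * (1 - 2 * P)) %*% wj) / L - g1^2  # d2 loglik_i / d eta_i^2
    H <- crossprod(X, X * (-curv))
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    t <- 1
    repeat {
      cand <- beta + t * step
      nll_new <- nll_at(cand)
      if (nll_new <= nll_cur + 1e-12 || t < 1e-6) break
      t <- t / 2
    }
    moved <- max(abs(t * step))
    beta <- cand
    nll_cur <- min(nll_new, nll_cur)
    if (moved < 1e-10) { converged <- TRUE; break }
  }
  list(beta = beta, nll = nll_cur, converged = converged)
}

#' Fit the GSEM with a latent fatigue disturbance
#'
#' Extends the composite model by giving fatigue its own disturbance,
#' `F = sum(b * M) + zeta`, `zeta ~ N(0, psi)`. The mediator equations are
#' unchanged; the outcome likelihood marginalizes over `zeta` by
#' Gauss-Hermite quadrature and is maximized by profiling over the
#' disturbance scale with a damped-Newton inner fit (analytic gradient and
#' Hessian).
#'
#' With a single binary outcome measurement per respondent, `psi` is
#' identified only through the difference in shape between a logistic and a
#' logistic-normal marginal link, so its profile likelihood is nearly flat.
#' The fitted `psi` is therefore retained only when it improves the
#' log-likelihood beyond the 5% critical value of the boundary-mixture
#' likelihood-ratio test (`0.5 chi2_0 + 0.5 chi2_1`); otherwise the boundary
#' fit `psi = 0` is reported with `meta$psi_boundary = TRUE` (a flag, not an
#' error), and the achieved gain is in `meta$psi_lrt_gain`. Standard errors
#' are not reported in this mode; the bootstrap is the inferential
#' instrument.
#'
#' @param records survey data.frame.
#' @param model a valid `gsem_model` (mode `"latent_disturbance"`).
#' @param quadrature_nodes number of Gauss-Hermite nodes (default 21).
#' @param psi optionally fix the disturbance variance instead of estimating
#'   it; `psi = 0` reproduces the composite fit.
#' @return a `gsem_coefs` table; `attr(, "meta")` additionally carries `psi`,
#'   `psi_boundary`, `quadrature_nodes`, `converged`.
#' @export
fit_latent <- function(records, model = default_model(mode = "latent_disturbance"),
                       quadrature_nodes = 21L, psi = NULL) {
  ctx <- build_fit_context(records, model)
  eq <- fit_equations(ctx, se = TRUE)        # composite fit = starting values
  gh <- pracma::gaussHermite(quadrature_nodes)
  zj <- sqrt(2) * gh$x
  wj <- gh$w / sqrt(pi)
  X <- eq$outcome_design
  y <- eq$outcome_y
  p <- ncol(X)
  s_fixed <- if (!is.null(psi)) abs(ctx$loading) * sqrt(psi) else NULL
  # Profile the marginal likelihood over the disturbance scale s with a
  # damped-Newton inner fit in beta (warm-started). With one Bernoulli draw
  # per respondent, s is identified only through the shape difference
  # between the logistic and the logistic-normal marginal link, so the
  # profile is nearly flat; the fitted psi is retained only if it improves
  # the log-likelihood beyond the 5% critical value of the boundary-mixture
  # LRT (0.5 chi2_0 + 0.5 chi2_1, i.e. a gain of qchisq(.90, 1)/2 = 1.35),
  # otherwise the boundary fit psi = 0 is reported with a flag.
  beta_cur <- unname(eq$outcome_coef)
  conv_cur <- TRUE
  profile_nll <- function(s) {
    o <- gh_profile_fit(X, y, zj, wj, s, beta_cur)
    beta_cur <<- o$beta
    conv_cur <<- o$converged
    o$nll
  }
  if (is.null(s_fixed)) {
    at0 <- -eq$loglik_outcome            # s = 0 reduces to the IRLS optimum
    beta0 <- beta_cur
    os <- optimize(profile_nll, c(0, 3), tol = 1e-3)
    lrt_gain <- at0 - os$objective
    if (lrt_gain <= qchisq(0.90, 1) / 2) {
      s_hat <- 0
      value <- at0
      beta_cur <- beta0
      conv_cur <- TRUE
    } else {
      s_hat <- os$minimum
      value <- profile_nll(s_hat)            # re-sync beta with chosen s
    }
  } else {
    s_hat <- s_fixed
    value <- if (s_fixed == 0) {
      beta_cur <- unname(eq$outcome_coef)
      -eq$loglik_outcome
    } else profile_nll(s_fixed)
    lrt_gain <- NA_real_
  }
  opt <- list(par = beta_cur, value = value,
              convergence = if (conv_cur) 0L else 1L)
  beta <- setNames(opt$par[seq_len(p)], colnames(X))
  psi_hat <- (s_hat / abs(ctx$loading))^2
  # overwrite outcome-equation entries with the marginal-likelihood estimates
  est <- eq$est
  est[edge_key(ctx$out_direct, ctx$outcome)] <- beta[ctx$out_direct]
  est[edge_key(ctx$lat_parents, ctx$latent)] <-
    beta[ctx$lat_parents] / ctx$loading
  eq$est <- est
  eq$se <- eq$se * NA_real_                  # bootstrap is the instrument here
  eq$intercepts[ctx$outcome] <- beta[["(Intercept)"]]
  eq$loglik_outcome <- -opt$value
  eq$loglik <- eq$loglik_mediators - opt$value
  tab <- new_coef_table(ctx, eq, meta_extra = list(
    psi = psi_hat,
    psi_lrt_gain = lrt_gain,
    psi_boundary = is.null(s_fixed) && s_hat < 1e-3,
    psi_fixed = !is.null(psi),
    quadrature_nodes = as.integer(quadrature_nodes),
    optim_convergence = opt$convergence))
  meta <- attr(tab, "meta")
  meta$converged <- opt$convergence == 0
  attr(tab, "meta") <- meta
  if (opt$convergence != 0)
    warnf("latent-disturbance optimizer did not converge (code %d)",
          opt$convergence)
  tab
}

#' Fit a GSEM, dispatching on the model's estimation mode
#'
#' @param records survey data.frame.
#' @param model a valid `gsem_model`.
#' @param ... passed to [fit_latent()] in latent-disturbance mode.
#' @return a `gsem_coefs` table.
#' @export
fit_gsem <- function(records, model = default_model(), ...) {
  switch(model$mode,
         composite = fit_composite(records, model),
         latent_disturbance = fit_latent(records, model, ...),
         stopf("unknown mode '%s'", model$mode))
}

#' Build a coefficient table by hand
#'
#' Useful for feeding published point estimates through the effect
#' decomposition without refitting.
#'
#' @param source,target character vectors of edge endpoints.
#' @param estimate numeric coefficient per edge.
#' @param fixed logical; `TRUE` for edges fixed by constraint.
#' @param se optional standard errors.
#' @return a `gsem_coefs` data.frame.
#' @export
coef_table <- function(source, target, estimate, fixed = FALSE, se = NA_real_) {
  tab <- data.frame(source = source, target = target,
                    estimate = estimate, se = se,
                    fixed = rep_len(fixed, length(source)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("gsem_coefs", "data.frame")
  tab
}

#' Add an odds-ratio column to a coefficient table
#'
#' `OR = exp(estimate)` for every estimated (non-fixed) edge into the
#' outcome; other rows get `NA` (reported as "-"), matching the convention
#' that odds ratios are only meaningful for log-odds coefficients of the
#' binary outcome equation.
#'
#' @param table a `gsem_coefs` table.
#' @param outcome outcome node name; inferred from the fit metadata when
#'   present.
#' @return the table with an `or` column.
#' @export
coefficients_to_or <- function(table, outcome = NULL) {
  meta <- attr(table, "meta")
  if (is.null(outcome))
    outcome <- if (!is.null(meta$model)) nodes_of_role(meta$model, "outcome")
               else "near_miss"
  table$or <- ifelse(table$target == outcome & !table$fixed,
                     exp(table$estimate), NA_real_)
  table
}

#' Write a coefficient table to a delimited file
#'
#' Columns `source, target, estimate, se, or, fixed` in the canonical report
#' order; a `#` header line records fit metadata.
#'
#' @param table a `gsem_coefs` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coef_table <- function(table, path) {
  tab <- if ("or" %in% names(table)) table else coefficients_to_or(table)
  meta <- attr(tab, "meta")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# gsemmed coefficients; mode=%s; n=%d; loglik=%.6f",
                       meta$mode, meta$n, meta$loglik), con)
  write.csv(tab[, c("source", "target", "estimate", "se", "or", "fixed")],
            con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.gsem_coefs <- function(x, digits = 3, ...) {
  meta <- attr(x, "meta")
  if (!is.null(meta))
    cat(sprintf("GSEM fit (%s mode), n = %d, log-likelihood = %.2f\n",
                meta$mode, meta$n, meta$loglik))
  if (!is.null(meta$psi))
    cat(sprintf("latent disturbance psi = %.4f%s\n", meta$psi,
                if (isTRUE(meta$psi_boundary)) " (at boundary)" else ""))
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  if (!is.null(df$se)) df$se <- round(df$se, digits)
  if (!is.null(df$or)) df$or <- round(df$or, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
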