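# Nonparametric bootstrap of the full pipeline: resample respondents with
# replacement, refit every equation, re-decompose the effects, and take
# percentile confidence intervals of each coefficient and effect on the
# log-odds scale. Significance follows the rule that the 95% CI of a
# difference measure must not include 0 (boundary inclusive = not
# significant); because percentile intervals commute with monotone
# transforms, the OR-scale interval is exactly the exponentiated log-scale
# interval.

#' Percentile confidence interval
#'
#' Empirical quantiles at `(1 - level) / 2` and `1 - (1 - level) / 2` of the
#' replicate draws, using the order-statistic quantile with linear
#' interpolation (R's default type 7). At small replicate counts percentile
#' CIs depend on the quantile rule, hence it is pinned down here.
#'
#' @param draws numeric vector of replicate values (length >= 2).
#' @param level coverage probability in (0, 1), default 0.95.
#' @return numeric `c(low, high)`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2) stopf("need at least 2 replicate draws")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  unname(quantile(draws, c(alpha, 1 - alpha), type = 7))
}

#' Significance flags from percentile CIs
#'
#' A quantity is significant iff its log/coefficient-scale CI excludes 0
#' strictly: `low > 0` or `high < 0`. A bound exactly at 0 is NOT significant
#' (the interval then includes 0). Equivalent to the OR-scale CI excluding 1.
#'
#' @param result a `gsem_boot` object (or its `ci` data.frame).
#' @return the input with the `significant` column (re)computed.
#' @export
flag_significance <- function(result) {
  ci <- if (inherits(result, "gsem_boot")) result$ci else result
  ci$significant <- ci$low > 0 | ci$high < 0
  if (inherits(result, "gsem_boot")) {
    result$ci <- ci
    result
  } else ci
}

#' Bootstrap the fitted model and effect decomposition
#'
#' Draws `B` resamples of the analyzed respondents with replacement (whole
#' rows, preserving the joint mediator-outcome structure), refits all
#' equations on each resample, recomputes the effect decomposition, and
#' summarizes each coefficient and each effect with a percentile CI and
#' significance flag. Replicates where the logistic fit fails (separation or
#' non-convergence, typical of very small strata) are dropped and counted;
#' the run aborts if more than 5% of replicates fail, which signals a fit too
#' fragile to summarize.
#'
#' @param records survey data.frame (analyzed rows).
#' @param model a valid `gsem_model` (composite mode is bootstrapped; for
#'   latent-disturbance models the composite equations are the resampled
#'   statistic as well, the disturbance being a point-estimate refinement).
#' @param B number of bootstrap replicates (>= 2); 1000 by default.
#' @param seed integer seed; the replicate stream is fully determined by it.
#' @param level CI coverage probability.
#' @param stratify_by `NULL` (plain resampling), `"exposure"`/`TRUE` to
#'   resample within working-hour categories (stabilizes small exposure
#'   cells in subgroup runs), or the name of a model variable to stratify
#'   on.
#' @return a `gsem_boot` list: `B`, `seed`, `point` (named vector of full-
#'   sample coefficients and log-scale effects), `draws` (B x K replicate
#'   matrix, failed rows NA), `ci` (data.frame `quantity`, `estimate`, `low`,
#'   `high`, `significant`), `n_failed`, plus the full-sample `coefficients`
#'   and `effects` objects. Effect quantities are keyed
#'   `"level|effect_type"` or `"level|indirect|mediator"`.
#' @export
bootstrap_gsem <- function(records, model = default_model(), B = 1000L,
                           seed = 1L, level = 0.95, stratify_by = NULL) {
  if (B < 2) stopf("B must be >= 2")
  if (!nrow(records)) stopf("records is empty")
  ctx <- build_fit_context(records, model)
  paths <- enumerate_paths(model)
  point_eq <- fit_equations(ctx, se = FALSE)
  point <- c(point_eq$est, path_effects(point_eq$est, paths))
  K <- length(point)
  n <- ctx$n
  strata <- NULL
  if (isTRUE(stratify_by) || identical(stratify_by, "exposure")) {
    ex <- nodes_of_role(model, "exposure_level")
    strata <- split(seq_len(n),
                    apply(ctx$data[, ex, drop = FALSE], 1, paste, collapse = ""))
  } else if (!is.null(stratify_by)) {
    if (!stratify_by %in% colnames(ctx$data))
      stopf("stratify_by column '%s' is not a model variable", stratify_by)
    strata <- split(seq_len(n), ctx$data[, stratify_by])
  }
  draws <- matrix(NA_real_, B, K, dimnames = list(NULL, names(point)))
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(B)) {
      idx <- if (is.null(strata)) sample.int(n, n, replace = TRUE)
             else unlist(lapply(strata, function(s)
               s[sample.int(length(s), length(s), replace = TRUE)]),
               use.names = FALSE)
      rep_eq <- tryCatch(fit_equations(ctx, idx, se = FALSE,
                                       start = unname(point_eq$outcome_coef)),
                         error = function(e) NULL)
      if (is.null(rep_eq)) {
        n_failed <- n_failed + 1L
      } else {
        draws[r, ] <- c(rep_eq$est, path_effects(rep_eq$est, paths))
      }
    }
  })
  if (n_failed > 0.05 * B)
    stopf("%d of %d bootstrap replicates failed to converge (> 5%%); the fit is too fragile to bootstrap", n_failed, B)
  cis <- t(apply(draws, 2, function(x) percentile_ci(x, level)))
  ci <- data.frame(quantity = names(point), estimate = unname(point),
                   low = cis[, 1], high = cis[, 2],
                   stringsAsFactors = FALSE, row.names = NULL)
  res <- structure(list(B = as.integer(B), seed = as.integer(seed),
                        level = level, point = point, draws = draws,
                        ci = ci, n_failed = n_failed,
                        coefficients = fit_gsem(records, model),
                        effects = NULL),
                   class = "gsem_boot")
  res$effects <- decompose_effects(res$coefficients, paths)
  flag_significance(res)
}

#' Extract effect-scale CIs from a bootstrap result
#'
#' @param boot a `gsem_boot` object.
#' @return the `ci` rows for decomposition quantities (keys containing `|`),
#'   suitable for [format_effect_table()] / [write_effects()].
#' @export
effect_cis <- function(boot) {
  boot$ci[grepl("|", boot$ci$quantity, fixed = TRUE), , drop = FALSE]
}

#' Persist bootstrap replicate draws for audit
#'
#' @param boot a `gsem_boot` object.
#' @param path output file (CSV; one row per replicate, failed rows empty).
#' @return `path`, invisibly.
#' @export
write_boot_draws <- function(boot, path) {
  write.csv(as.data.frame(boot$draws), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.gsem_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: B = %d (failed: %d), seed = %d, %.0f%% percentile CIs\n",
              x$B, x$n_failed, x$seed, 100 * x$level))
  print(format_effect_table(x$effects, cis = effect_cis(x)),
        row.names = FALSE)
  invisible(x)
}
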