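# Product-of-coefficients effect decomposition. Each enumerated exposure ->
# outcome path contributes the product of its edge coefficients (fixed
# constraints included) on the log-odds scale; indirect effects are grouped
# by the first mediator on the path (the reporting convention of the study's
# effect tables), the total effect is direct + sum of indirect, and odds
# ratios are exp() of the log-odds effects, taken once at the end.

effect_key <- function(level, type, mediator = NA_character_) {
  n <- max(length(level), length(type), length(mediator))
  level <- rep_len(level, n)
  type <- rep_len(type, n)
  mediator <- rep_len(as.character(mediator), n)
  ifelse(type == "indirect" & !is.na(mediator),
         paste(level, type, mediator, sep = "|"),
         paste(level, type, sep = "|"))
}

# log-scale effect vector from a named coefficient vector and a path set;
# used by both decompose_effects() and the bootstrap fast path.
path_effects <- function(estimates, paths) {
  prods <- vapply(seq_len(nrow(paths)), function(i) {
    nd <- paths$nodes[[i]]
    keys <- edge_key(nd[-length(nd)], nd[-1L])
    miss <- setdiff(keys, names(estimates))
    if (length(miss))
      stopf("path '%s' uses edges absent from the coefficient table: %s",
            paths$path[i], paste(miss, collapse = ", "))
    prod(estimates[keys])
  }, 0)
  out <- numeric(0)
  for (lv in unique(paths$level)) {
    sel <- paths$level == lv
    direct <- sum(prods[sel & paths$first_mediator == "direct"])
    meds <- sort(unique(paths$first_mediator[sel &
                                             paths$first_mediator != "direct"]))
    ind <- vapply(meds, function(m)
      sum(prods[sel & paths$first_mediator == m]), 0)
    out <- c(out,
             setNames(direct, effect_key(lv, "direct")),
             setNames(ind, effect_key(lv, "indirect", meds)),
             setNames(direct + sum(ind), effect_key(lv, "total")))
  }
  out
}

#' Decompose exposure effects into direct, indirect and total
#'
#' For each exposure level, the direct effect is the exposure -> outcome
#' coefficient; each indirect effect is the sum, over all enumerated paths
#' whose first intermediate node is a given mediator, of the product of the
#' path's edge coefficients (including fixed constraints); the total effect
#' is direct plus all indirect effects. All arithmetic is on the log-odds
#' scale; odds ratios are obtained by a single exponentiation, so
#' `OR_total = OR_direct * prod(OR_indirect)` holds to machine precision.
#' The reference level appears with all effects 0 (OR 1).
#'
#' @param table a `gsem_coefs` coefficient table covering every path edge.
#' @param paths a `gsem_paths` path set from [enumerate_paths()].
#' @return a `gsem_effects` data.frame with columns `level`, `effect_type`
#'   (`direct`/`indirect`/`total`), `first_mediator` (`NA` except for
#'   indirect rows), `log_effect`, `or`. Per-full-path contributions are kept
#'   in `attr(, "path_contributions")`.
#' @export
decompose_effects <- function(table, paths) {
  estimates <- setNames(table$estimate, edge_key(table$source, table$target))
  eff <- path_effects(estimates, paths)
  parts <- strsplit(names(eff), "|", fixed = TRUE)
  ref <- attr(paths, "reference_level")
  res <- data.frame(
    level = vapply(parts, `[`, "", 1L),
    effect_type = vapply(parts, `[`, "", 2L),
    first_mediator = vapply(parts, function(p)
      if (length(p) > 2L) p[3L] else NA_character_, ""),
    log_effect = unname(eff),
    stringsAsFactors = FALSE)
  if (!is.null(ref)) {
    meds <- sort(unique(res$first_mediator[!is.na(res$first_mediator)]))
    res <- rbind(data.frame(level = ref,
                            effect_type = c("direct", rep("indirect",
                                                          length(meds)), "total"),
                            first_mediator = c(NA, meds, NA),
                            log_effect = 0,
                            stringsAsFactors = FALSE),
                 res)
  }
  res$or <- exp(res$log_effect)
  contrib <- data.frame(
    level = paths$level,
    first_mediator = paths$first_mediator,
    path = paths$path,
    log_effect = vapply(seq_len(nrow(paths)), function(i) {
      nd <- paths$nodes[[i]]
      prod(estimates[edge_key(nd[-length(nd)], nd[-1L])])
    }, 0),
    stringsAsFactors = FALSE)
  attr(res, "path_contributions") <- contrib
  attr(res, "reference_level") <- ref
  attr(res, "level_map") <- attr(paths, "level_map")
  class(res) <- c("gsem_effects", "data.frame")
  res
}

or_cell <- function(or, low = NA, high = NA) {
  if (is.na(low)) sprintf("%.2f", or)
  else sprintf("%.2f (%.2f, %.2f)", or, low, high)
}

#' Format an effect decomposition as a report table
#'
#' One row per exposure level (reference first, rendered
#' `"1.00 (reference)"`), one column for the direct effect, one per
#' first-mediator indirect effect, and one for the total effect; odds ratios
#' rounded to 2 decimals with optional percentile CIs appended as
#' `"OR (low, high)"`. Unrounded values remain available in the
#' `gsem_effects` object itself.
#'
#' @param decomp a `gsem_effects` decomposition.
#' @param cis optional data.frame with columns `quantity` (effect keys as in
#'   the bootstrap result), `low`, `high` on the log scale.
#' @return a data.frame of display strings.
#' @export
format_effect_table <- function(decomp, cis = NULL) {
  ref <- attr(decomp, "reference_level")
  lm_ <- attr(decomp, "level_map")
  levels_ <- unique(decomp$level)
  meds <- sort(unique(decomp$first_mediator[!is.na(decomp$first_mediator)]))
  ci_for <- function(key) {
    if (is.null(cis)) return(c(NA, NA))
    i <- match(key, cis$quantity)
    if (is.na(i)) c(NA, NA) else exp(c(cis$low[i], cis$high[i]))
  }
  cell <- function(lv, type, med = NA) {
    if (!is.null(ref) && lv == ref) return("1.00 (reference)")
    row <- decomp$log_effect[decomp$level == lv & decomp$effect_type == type &
                             (is.na(med) | decomp$first_mediator %in% med)]
    ci <- ci_for(effect_key(lv, type, med))
    or_cell(exp(row[1]), ci[1], ci[2])
  }
  out <- data.frame(
    level = vapply(levels_, function(lv)
      if (!is.null(lm_) && lv %in% names(lm_)) lm_[[lv]] else lv, ""),
    direct = vapply(levels_, cell, "", type = "direct"),
    stringsAsFactors = FALSE)
  for (m in meds)
    out[[paste0("indirect_", m)]] <-
      vapply(levels_, cell, "", type = "indirect", med = m)
  out$total <- vapply(levels_, cell, "", type = "total")
  rownames(out) <- NULL
  out
}

#' Write an effect decomposition to a delimited file
#'
#' Long format with columns
#' `level, effect_type, first_mediator, log_effect, or, ci_low, ci_high`
#' (CI columns on the OR scale, empty when no bootstrap result is supplied);
#' unrounded values are written.
#'
#' @param decomp a `gsem_effects` decomposition.
#' @param path output file.
#' @param cis optional CI data.frame as in [format_effect_table()].
#' @return `path`, invisibly.
#' @export
write_effects <- function(decomp, path, cis = NULL) {
  out <- as.data.frame(decomp)
  out$ci_low <- out$ci_high <- NA_real_
  if (!is.null(cis)) {
    keys <- effect_key(out$level, out$effect_type, out$first_mediator)
    i <- match(keys, cis$quantity)
    out$ci_low <- exp(cis$low[i])
    out$ci_high <- exp(cis$high[i])
  }
  write.csv(out[, c("level", "effect_type", "first_mediator",
                    "log_effect", "or", "ci_low", "ci_high")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.gsem_effects <- function(x, ...) {
  cat("Effect decomposition (odds-ratio scale):\n")
  print(format_effect_table(x), row.names = FALSE)
  invisible(x)
}
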