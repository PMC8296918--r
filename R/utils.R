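#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm glm lm.fit glm.fit binomial coef logLik plogis qlogis
#'   quantile rnorm runif rbinom sd uniroot optim setNames complete.cases
#'   vcov dnorm var chisq.test pchisq qchisq
#' @importFrom utils write.csv read.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_key <- function(from, to) paste0(from, "->", to)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber the user's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
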