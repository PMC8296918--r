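# Declarative structural-model graphs: construction, validation, path
# enumeration. The model is a DAG whose nodes carry roles (exposure dummy,
# mediator, latent composite, outcome, covariate); indirect effects are read
# off the enumerated exposure->outcome paths.

#' Construct a structural mediation model graph
#'
#' A `gsem_model` is a directed acyclic graph over typed nodes. Exposure
#' levels are dummy variables against an explicit reference level; mediators
#' feed a single latent composite (fatigue) whose loading on the outcome is
#' fixed to set the latent scale; covariates adjust the outcome equation.
#'
#' @param nodes data.frame with columns `name`, `role`; roles are
#'   `"exposure_level"`, `"mediator"`, `"latent"`, `"outcome"`, `"covariate"`.
#' @param edges data.frame with columns `from`, `to`.
#' @param constraints named numeric vector of fixed edge coefficients; names
#'   are `"from->to"` keys. The latent -> outcome edge must be constrained
#'   (conventionally to 1) to identify the latent scale.
#' @param mode estimation mode, `"composite"` (latent is a deterministic
#'   weighted sum of mediators) or `"latent_disturbance"` (latent has its own
#'   normal disturbance, integrated out of the outcome likelihood).
#' @param reference_level name of the exposure category omitted from the
#'   dummies (it is not a node).
#' @param level_map named character vector mapping exposure node names (plus
#'   the reference level) to the category labels used in data files.
#' @return an object of class `gsem_model`.
#' @seealso [default_model()], [validate_model()], [enumerate_paths()]
#' @export
gsem_model <- function(nodes, edges, constraints = numeric(),
                       mode = c("composite", "latent_disturbance"),
                       reference_level, level_map = NULL) {
  mode <- match.arg(mode)
  nodes <- data.frame(name = as.character(nodes$name),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  constraints <- unlist(constraints)
  if (length(constraints) && is.null(names(constraints)))
    stopf("constraints must be a named vector with 'from->to' keys")
  structure(
    list(nodes = nodes, edges = edges,
         constraints = setNames(as.numeric(constraints), names(constraints)),
         mode = mode, reference_level = as.character(reference_level),
         level_map = level_map),
    class = "gsem_model")
}

#' Default working-hours / near-miss mediation model
#'
#' Builds the base model: three working-hour dummies (41-50, 51-60, >=61 h/w;
#' reference 35-40 h/w) point at each of three mediators (job-related stress,
#' sleep problems, depressive symptoms) and directly at the near-miss
#' outcome; the mediators load on a latent fatigue composite whose loading on
#' the outcome is fixed at 1.00; male sex and age >= 35 adjust the outcome.
#'
#' @param mode estimation mode, see [gsem_model()].
#' @param covariates_to_mediators if `TRUE`, also adds covariate -> mediator
#'   edges so the mediator equations are covariate-adjusted. The default
#'   (`FALSE`) has covariates entering only the outcome equation.
#' @return a validated `gsem_model`.
#' @examples
#' m <- default_model()
#' nrow(m$nodes)  # 10
#' nrow(m$edges)  # 18
#' @export
default_model <- function(mode = "composite", covariates_to_mediators = FALSE) {
  exposures <- c("hours41_50", "hours51_60", "hours61plus")
  mediators <- c("job_stress", "sleep", "depression")
  covariates <- c("male", "age_ge35")
  nodes <- data.frame(
    name = c(exposures, mediators, "fatigue", "near_miss", covariates),
    role = c(rep("exposure_level", 3), rep("mediator", 3),
             "latent", "outcome", rep("covariate", 2)))
  edges <- rbind(
    expand.grid(from = exposures, to = mediators, stringsAsFactors = FALSE),
    data.frame(from = exposures, to = "near_miss"),
    data.frame(from = mediators, to = "fatigue"),
    data.frame(from = "fatigue", to = "near_miss"),
    data.frame(from = covariates, to = "near_miss"))
  if (covariates_to_mediators)
    edges <- rbind(edges, expand.grid(from = covariates, to = mediators,
                                      stringsAsFactors = FALSE))
  gsem_model(
    nodes = nodes, edges = edges,
    constraints = c("fatigue->near_miss" = 1.00),
    mode = mode,
    reference_level = "hours35_40",
    level_map = c(hours35_40 = "35-40", hours41_50 = "41-50",
                  hours51_60 = "51-60", hours61plus = ">=61"))
}

node_role <- function(model, name) {
  model$nodes$role[match(name, model$nodes$name)]
}

nodes_of_role <- function(model, role) {
  model$nodes$name[model$nodes$role %in% role]
}

parents_of <- function(model, name) {
  sort(model$edges$from[model$edges$to == name])
}

children_of <- function(model, name) {
  sort(model$edges$to[model$edges$from == name])
}

# Kahn topological sort; returns NULL if the graph has a cycle.
topo_sort <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (t in edges$to) indeg[t] <- indeg[t] + 1L
  order <- character(0)
  queue <- sort(names(indeg)[indeg == 0L])
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

#' Validate a structural model graph
#'
#' Checks every structural invariant and returns violations as messages
#' rather than raising, so configuration errors can be reported together.
#'
#' Invariants: edges reference declared nodes; the graph is acyclic; there is
#' exactly one outcome with out-degree 0; exposure dummies and covariates
#' have in-degree 0; there is exactly one latent node; mediators influence
#' the outcome only through the latent (no mediator -> outcome edge); the
#' latent -> outcome edge exists and carries a fixed constraint (otherwise
#' the latent scale is unidentified); the reference level is not itself a
#' dummy node.
#'
#' @param model a `gsem_model`.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_model <- function(model) {
  v <- character(0)
  nodes <- model$nodes$name
  if (anyDuplicated(nodes))
    v <- c(v, "duplicate node names")
  bad <- setdiff(unique(c(model$edges$from, model$edges$to)), nodes)
  if (length(bad))
    return(c(v, sprintf("edges reference undeclared nodes: %s",
                        paste(bad, collapse = ", "))))
  if (any(model$edges$from == model$edges$to))
    v <- c(v, "self-loop edge (cycle)")
  if (anyDuplicated(paste(model$edges$from, model$edges$to)))
    v <- c(v, "duplicate edges")
  if (is.null(topo_sort(nodes, model$edges)))
    v <- c(v, "graph contains a cycle")

  outcomes <- nodes_of_role(model, "outcome")
  if (length(outcomes) != 1) {
    v <- c(v, sprintf("expected exactly 1 outcome node, found %d",
                      length(outcomes)))
  } else {
    if (any(model$edges$from == outcomes))
      v <- c(v, "outcome node has outgoing edges")
  }
  for (x in nodes_of_role(model, c("exposure_level", "covariate")))
    if (any(model$edges$to == x))
      v <- c(v, sprintf("node '%s' (%s) has incoming edges", x,
                        node_role(model, x)))

  latents <- nodes_of_role(model, "latent")
  if (length(latents) != 1) {
    v <- c(v, sprintf("expected exactly 1 latent node, found %d",
                      length(latents)))
  } else if (length(outcomes) == 1) {
    key <- edge_key(latents, outcomes)
    has_edge <- any(model$edges$from == latents & model$edges$to == outcomes)
    if (!has_edge)
      v <- c(v, "missing latent -> outcome edge")
    else if (!key %in% names(model$constraints))
      v <- c(v, sprintf(
        "unconstrained latent scale: edge %s needs a fixed coefficient", key))
  }
  if (length(outcomes) == 1) {
    meds <- nodes_of_role(model, "mediator")
    direct <- model$edges$from %in% meds & model$edges$to == outcomes
    if (any(direct))
      v <- c(v, sprintf(
        "mediator -> outcome edge not allowed (must pass through latent): %s",
        paste(edge_key(model$edges$from[direct], outcomes), collapse = ", ")))
  }
  if (model$reference_level %in% nodes)
    v <- c(v, "reference_level must not be an exposure dummy node")
  bad_con <- setdiff(names(model$constraints),
                     edge_key(model$edges$from, model$edges$to))
  if (length(bad_con))
    v <- c(v, sprintf("constraints on absent edges: %s",
                      paste(bad_con, collapse = ", ")))
  v
}

assert_valid_model <- function(model) {
  v <- validate_model(model)
  if (length(v))
    stopf("invalid model:\n  - %s", paste(v, collapse = "\n  - "))
  invisible(model)
}

#' Enumerate exposure-to-outcome paths
#'
#' Lists every simple directed path from each exposure dummy to the outcome,
#' grouped by the first intermediate node on the path ("first mediator", the
#' reporting convention for indirect effects); the bare exposure -> outcome
#' edge is labelled `"direct"`. Paths are returned in lexicographic order of
#' their node sequences, so enumeration is deterministic.
#'
#' @param model a valid `gsem_model`.
#' @return a `gsem_paths` data.frame with columns `level` (exposure node),
#'   `first_mediator` (`"direct"` or mediator name), `path` (display string),
#'   and a list-column `nodes` with the node sequences.
#' @export
enumerate_paths <- function(model) {
  assert_valid_model(model)
  outcome <- nodes_of_role(model, "outcome")
  out <- list()
  for (x in nodes_of_role(model, "exposure_level")) {
    acc <- list()
    walk <- function(node, trail) {
      if (node == outcome) {
        acc[[length(acc) + 1L]] <<- trail
        return(invisible())
      }
      for (nxt in children_of(model, node))
        if (!nxt %in% trail) walk(nxt, c(trail, nxt))
    }
    walk(x, x)
    keyed <- vapply(acc, paste, "", collapse = "\x01")
    acc <- acc[order(keyed)]
    out[[x]] <- acc
  }
  res <- do.call(rbind, lapply(names(out), function(x) {
    paths <- out[[x]]
    data.frame(
      level = rep(x, length(paths)),
      first_mediator = vapply(paths, function(p)
        if (length(p) == 2L) "direct" else p[2L], ""),
      path = vapply(paths, paste, "", collapse = " -> "),
      stringsAsFactors = FALSE)
  }))
  res$nodes <- I(unlist(lapply(out, function(p) p), recursive = FALSE,
                        use.names = FALSE))
  attr(res, "reference_level") <- model$reference_level
  attr(res, "level_map") <- model$level_map
  class(res) <- c("gsem_paths", "data.frame")
  res
}

#' Add edges to a model
#'
#' Convenience for sensitivity variants (e.g. mediator -> mediator paths).
#'
#' @param model a `gsem_model`.
#' @param from,to character vectors of equal length.
#' @return the modified model (not revalidated; call [validate_model()]).
#' @export
add_model_edges <- function(model, from, to) {
  model$edges <- rbind(model$edges,
                       data.frame(from = from, to = to,
                                  stringsAsFactors = FALSE))
  model
}

#' Add outcome covariates to a model
#'
#' Adds nodes with role `covariate` and covariate -> outcome edges, as used
#' by the sensitivity variant that adjusts for night/shift work and the
#' fatigue-recovery score.
#'
#' @param model a `gsem_model`.
#' @param names covariate node names (must match data column names).
#' @return the modified model.
#' @export
add_model_covariates <- function(model, names) {
  outcome <- nodes_of_role(model, "outcome")
  model$nodes <- rbind(model$nodes,
                       data.frame(name = names, role = "covariate"))
  add_model_edges(model, names, rep(outcome, length(names)))
}

#' Read / write a model configuration file
#'
#' Serializes a `gsem_model` to a human-diffable YAML or JSON document with
#' keys `nodes`, `edges`, `constraints`, `mode`, `reference_level`,
#' `level_map`. Format is chosen by file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param model a `gsem_model`.
#' @param path file path.
#' @return `read_model_config` returns a `gsem_model`; `write_model_config`
#'   returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  doc <- list(
    nodes = lapply(seq_len(nrow(model$nodes)), function(i)
      list(name = model$nodes$name[i], role = model$nodes$role[i])),
    edges = lapply(seq_len(nrow(model$edges)), function(i)
      list(from = model$edges$from[i], to = model$edges$to[i])),
    constraints = as.list(model$constraints),
    mode = model$mode,
    reference_level = model$reference_level,
    level_map = as.list(model$level_map %||% list()))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  lm_ <- unlist(doc$level_map)
  gsem_model(
    nodes = data.frame(name = vapply(doc$nodes, `[[`, "", "name"),
                       role = vapply(doc$nodes, `[[`, "", "role")),
    edges = data.frame(from = vapply(doc$edges, `[[`, "", "from"),
                       to = vapply(doc$edges, `[[`, "", "to")),
    constraints = unlist(doc$constraints) %||% numeric(),
    mode = doc$mode,
    reference_level = doc$reference_level,
    level_map = if (length(lm_)) lm_ else NULL)
}

#' Export a model graph as Graphviz DOT
#'
#' Latent nodes are drawn as circles (ellipses), observed nodes as boxes;
#' fixed edges are annotated with their constraint value.
#'
#' @param model a `gsem_model`.
#' @param path optional file to write to.
#' @return the DOT source as a character scalar (invisibly if written).
#' @export
model_to_dot <- function(model, path = NULL) {
  shape <- ifelse(model$nodes$role == "latent", "ellipse", "box")
  lines <- c(
    "digraph gsem {",
    "  rankdir=LR;",
    sprintf('  "%s" [shape=%s];', model$nodes$name, shape),
    vapply(seq_len(nrow(model$edges)), function(i) {
      key <- edge_key(model$edges$from[i], model$edges$to[i])
      lab <- if (key %in% names(model$constraints))
        sprintf(' [label="fixed %.2f"]', model$constraints[[key]]) else ""
      sprintf('  "%s" -> "%s"%s;', model$edges$from[i], model$edges$to[i], lab)
    }, ""),
    "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

#' @export
print.gsem_model <- function(x, ...) {
  cat(sprintf("gsem_model: %d nodes, %d edges, mode = %s\n",
              nrow(x$nodes), nrow(x$edges), x$mode))
  for (r in unique(x$nodes$role))
    cat(sprintf("  %s: %s\n", r,
                paste(x$nodes$name[x$nodes$role == r], collapse = ", ")))
  cat(sprintf("  reference level: %s\n", x$reference_level))
  if (length(x$constraints))
    cat(sprintf("  fixed: %s\n",
                paste(sprintf("%s = %.2f", names(x$constraints),
                              x$constraints), collapse = ", ")))
  invisible(x)
}
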