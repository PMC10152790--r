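#' Terminal node of a pathway
#'
#' A terminal node represents a complete patient pathway over the 5-year
#' follow-up horizon. It carries the per-year per-payer costs C(A1)..C(A5)
#' and a death flag used to aggregate model mortality. Optionally it keeps
#' the procedure schedule (expected procedure counts per follow-up year) it
#' was folded from, so that probabilistic sensitivity analysis can recompute
#' the costs from a redrawn cost table.
#'
#' @param pathway_id Unique pathway identifier.
#' @param per_year_costs Costs for follow-up years 1..5: a 5 x 3 numeric
#'   matrix (columns `tpp`, `oop`, `bdl`, thousand LBP) or a list of 5
#'   [payer_costs()] vectors. Zero vectors are allowed.
#' @param is_death Logical; does this pathway end in death within the horizon?
#' @param schedule Optional procedures x 5 matrix of expected procedure
#'   counts per year (rownames are procedure ids).
#' @param stage Optional stage label used for per-stage cost breakdowns.
#' @return An object of class `terminal_node`.
#' @export
terminal_node <- function(pathway_id, per_year_costs = NULL, is_death = FALSE,
                          schedule = NULL, stage = NULL) {
  if (is.null(per_year_costs)) {
    per_year_costs <- matrix(0, 5, 3, dimnames = list(NULL, payer_names))
  }
  if (is.list(per_year_costs)) {
    per_year_costs <- do.call(rbind, lapply(per_year_costs, function(v) {
      unclass(as_payer_costs(v))
    }))
  }
  per_year_costs <- as.matrix(per_year_costs)
  if (nrow(per_year_costs) != 5 || ncol(per_year_costs) != 3) {
    stop("per_year_costs must cover exactly 5 follow-up years x 3 payers",
         call. = FALSE)
  }
  colnames(per_year_costs) <- payer_names
  if (any(!is.finite(per_year_costs)) || any(per_year_costs < 0)) {
    stop("terminal costs must be non-negative and finite", call. = FALSE)
  }
  if (!is.null(schedule)) {
    schedule <- as.matrix(schedule)
    stopifnot(ncol(schedule) == 5, !is.null(rownames(schedule)))
  }
  structure(
    list(pathway_id = as.character(pathway_id),
         per_year_costs = per_year_costs,
         is_death = isTRUE(is_death),
         schedule = schedule,
         stage = stage),
    class = "terminal_node"
  )
}

#' Chance node
#'
#' A chance node splits the cohort over two or more mutually exclusive
#' branches. Branch probabilities are point estimates; each entry may instead
#' be a [beta_pert_spec()] whose mode is taken as the point estimate once the
#' tree is resolved. The optional `dist` argument controls how the node is
#' redrawn during probabilistic sensitivity analysis:
#' `"auto"` (default) applies the standard rule — Beta-PERT per branch for
#' two branches, Dirichlet for three or more; `"fixed"` freezes the node; a
#' [dirichlet_spec()] supplies explicit concentration parameters.
#'
#' @param node_id Unique node identifier.
#' @param children List of child nodes (`chance_node` or `terminal_node`).
#' @param probs Numeric vector of branch probabilities (must sum to 1 within
#'   1e-9), or a list mixing numbers and `beta_pert_spec` objects.
#' @param dist `"auto"`, `"fixed"`, or a `dirichlet_spec`.
#' @return An object of class `chance_node`.
#' @export
chance_node <- function(node_id, children, probs, dist = "auto") {
  if (length(children) < 2) {
    stop(sprintf("chance node '%s' needs at least 2 branches", node_id),
         call. = FALSE)
  }
  if (!is.list(probs)) probs <- as.list(as.numeric(probs))
  if (length(probs) != length(children)) {
    stop(sprintf("node '%s': %d probabilities for %d branches", node_id,
                 length(probs), length(children)), call. = FALSE)
  }
  numeric_probs <- vapply(probs, is.numeric, logical(1))
  if (all(numeric_probs)) {
    p <- vapply(probs, as.numeric, numeric(1))
    if (any(p < 0) || any(p > 1)) {
      stop(sprintf("node '%s': probabilities outside [0,1]", node_id),
           call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("node '%s': branch probabilities sum to %.12g, not 1",
                   node_id, sum(p)), call. = FALSE)
    }
  }
  if (inherits(dist, "dirichlet_spec") &&
      length(dist$alphas) != length(children)) {
    stop(sprintf("node '%s': dirichlet spec length does not match branches",
                 node_id), call. = FALSE)
  }
  structure(
    list(node_id = as.character(node_id), children = children,
         probs = probs, dist = dist),
    class = "chance_node"
  )
}

is_terminal <- function(node) inherits(node, "terminal_node")

#' Decision tree
#'
#' The full pathway model: a chance-node root whose leaves are all terminal
#' nodes. Validity requires unique node/pathway ids and unit total
#' probability mass over the enumerated root-to-leaf paths.
#'
#' @param root A `chance_node`.
#' @param name Model label (scenario-agnostic).
#' @return An object of class `decision_tree`.
#' @export
decision_tree <- function(root, name = "model") {
  tree <- structure(list(root = root, name = name), class = "decision_tree")
  validate_tree(tree)
  tree
}

#' @export
print.decision_tree <- function(x, ...) {
  n_terms <- length(collect_terminals(x$root))
  cat(sprintf("<decision_tree> '%s': %d terminal pathways", x$name, n_terms))
  if (tree_resolved(x)) {
    paths <- enumerate_paths(x)
    deaths <- sum(vapply(paths, function(p) p$prob * p$terminal$is_death,
                         numeric(1)))
    cat(sprintf(", mortality %.1f%%", 100 * deaths))
  }
  cat("\n")
  invisible(x)
}

collect_terminals <- function(node) {
  if (is_terminal(node)) return(list(node))
  unlist(lapply(node$children, collect_terminals), recursive = FALSE)
}

collect_node_ids <- function(node) {
  if (is_terminal(node)) return(node$pathway_id)
  c(node$node_id, unlist(lapply(node$children, collect_node_ids)))
}

#' Validate a decision tree
#'
#' Checks unique ids, branch arity, probability ranges and — when all
#' probabilities are numeric — that each node's branch probabilities and the
#' total path probability mass sum to 1 within 1e-9.
#'
#' @param tree A `decision_tree`.
#' @return The tree, invisibly; errors describe the first violation.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  if (!inherits(tree$root, "chance_node")) {
    stop("tree root must be a chance node", call. = FALSE)
  }
  ids <- collect_node_ids(tree$root)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate node ids in tree: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (tree_resolved(tree)) {
    paths <- enumerate_paths(tree)
    mass <- sum(vapply(paths, `[[`, numeric(1), "prob"))
    if (abs(mass - 1) > 1e-9) {
      stop(sprintf("total path probability mass is %.12g, not 1", mass),
           call. = FALSE)
    }
  }
  invisible(tree)
}

tree_resolved <- function(tree) {
  node_resolved <- function(node) {
    if (is_terminal(node)) return(TRUE)
    all(vapply(node$probs, is.numeric, logical(1))) &&
      all(vapply(node$children, node_resolved, logical(1)))
  }
  node_resolved(tree$root)
}

#' Resolve distribution references to point estimates
#'
#' Replaces any `beta_pert_spec` branch probability by its mode, then
#' revalidates. Needed before deterministic evaluation of a tree whose
#' branches were declared through distribution specs.
#'
#' @param tree A `decision_tree`.
#' @return A resolved `decision_tree` (all probabilities numeric).
#' @export
resolve_tree <- function(tree) {
  resolve_node <- function(node) {
    if (is_terminal(node)) return(node)
    node$probs <- lapply(node$probs, function(p) {
      if (is.numeric(p)) p else if (inherits(p, "beta_pert_spec")) p$mode
      else stop(sprintf("node '%s': unresolvable branch probability",
                        node$node_id), call. = FALSE)
    })
    p <- unlist(node$probs)
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("node '%s': resolved probabilities sum to %.12g, not 1",
                   node$node_id, sum(p)), call. = FALSE)
    }
    node$children <- lapply(node$children, resolve_node)
    node
  }
  tree$root <- resolve_node(tree$root)
  validate_tree(tree)
  tree
}

numeric_probs <- function(node) {
  p <- node$probs
  bad <- !vapply(p, is.numeric, logical(1))
  if (any(bad)) {
    stop(sprintf("unresolved parameter in node '%s'", node$node_id),
         call. = FALSE)
  }
  vapply(p, as.numeric, numeric(1))
}

#' Enumerate root-to-leaf paths
#'
#' The evaluation oracle: multiplies branch probabilities along every
#' root-to-leaf path. Returned probabilities sum to 1 (within 1e-9) for any
#' valid resolved tree.
#'
#' @param tree A `decision_tree` with all probabilities resolved to numbers.
#' @return A list with one entry per path:
#'   `prob` (path probability), `terminal` (the `terminal_node`), and
#'   `edges` (a data frame of `node_id`, `branch` along the path).
#' @export
enumerate_paths <- function(tree) {
  out <- list()
  walk <- function(node, prob, edges) {
    if (is_terminal(node)) {
      out[[length(out) + 1L]] <<- list(prob = prob, terminal = node,
                                       edges = edges)
      return(invisible(NULL))
    }
    p <- numeric_probs(node)
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], prob * p[i],
           rbind(edges, data.frame(node_id = node$node_id, branch = i,
                                   stringsAsFactors = FALSE)))
    }
  }
  walk(tree$root, 1,
       data.frame(node_id = character(), branch = integer(),
                  stringsAsFactors = FALSE))
  out
}

#' Expected 5-year per-patient cost of a tree
#'
#' Recursive expectation: the probability-weighted, component-wise sum over
#' payers of each terminal's summed 5-year cost vector. Equals the
#' path-enumeration computation exactly (linearity).
#'
#' @param tree A resolved `decision_tree`.
#' @return A [payer_costs()] vector, thousand LBP per incident patient.
#' @export
expected_cost <- function(tree) {
  validate_tree(tree)
  ec <- function(node) {
    if (is_terminal(node)) return(colSums(node$per_year_costs))
    p <- numeric_probs(node)
    vals <- lapply(node$children, ec)
    Reduce(`+`, Map(function(pi, v) pi * v, p, vals))
  }
  v <- ec(tree$root)
  payer_costs(v[["tpp"]], v[["oop"]], v[["bdl"]])
}

#' Overall model mortality
#'
#' @param tree A resolved `decision_tree` with death flags on terminals.
#' @return The probability of following a pathway that ends in death.
#' @export
mortality_rate <- function(tree) {
  m <- function(node) {
    if (is_terminal(node)) return(as.numeric(node$is_death))
    p <- numeric_probs(node)
    sum(p * vapply(node$children, m, numeric(1)))
  }
  m(tree$root)
}

#' Annual national cost
#'
#' Under constant yearly incidence I, the national 1-year cost equals
#' I x (C(A1)+...+C(A5)) = I x (5-year per-patient cost), with no
#' discounting.
#'
#' @param incidence_per_year New cases per year (>= 0).
#' @param per_patient_cost A [payer_costs()] 5-year per-patient cost.
#' @return A [payer_costs()] vector, thousand LBP per year nationally.
#' @export
annual_national_cost <- function(incidence_per_year, per_patient_cost) {
  stopifnot(is.numeric(incidence_per_year), incidence_per_year >= 0)
  as_payer_costs(incidence_per_year * as_payer_costs(per_patient_cost))
}

#' Per-stage expected cost decomposition
#'
#' Sums path probability x 5-year terminal cost over the terminals tagged
#' with each stage label. Untagged terminals are pooled under `"(untagged)"`.
#'
#' @param tree A resolved `decision_tree` with stage tags on terminals.
#' @return A data frame with `stage`, `tpp`, `oop`, `bdl`, `total`
#'   (expected thousand LBP per patient).
#' @export
stage_costs <- function(tree) {
  paths <- enumerate_paths(tree)
  stages <- vapply(paths, function(p) {
    if (is.null(p$terminal$stage)) "(untagged)" else p$terminal$stage
  }, character(1))
  contrib <- t(vapply(paths, function(p) {
    p$prob * colSums(p$terminal$per_year_costs)
  }, numeric(3)))
  agg <- rowsum(contrib, group = stages)
  out <- data.frame(stage = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$total <- out$tpp + out$oop + out$bdl
  out
}
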