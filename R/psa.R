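#' PSA configuration
#'
#' @param n_runs Number of Monte Carlo runs (default 100,000).
#' @param seed Root seed. Every distribution parameter draws from its own
#'   hierarchical sub-stream derived from this seed and the parameter's id,
#'   so adding a parameter never perturbs the draws of the others.
#' @param ci_level Percentile confidence level (default 0.95); `NULL`
#'   disables interval reporting.
#' @param alpha_scale Scale applied to branch probability estimates to form
#'   Dirichlet concentration parameters under the automatic rule (default
#'   100: estimates elicited as percentages are used as-is).
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_runs = 100000, seed = 1, ci_level = 0.95,
                       alpha_scale = 100) {
  stopifnot(n_runs >= 1, is.numeric(seed))
  if (!is.null(ci_level) && (ci_level <= 0 || ci_level >= 1)) {
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 ci_level = ci_level, alpha_scale = alpha_scale),
            class = "psa_config")
}

# stable 31-bit string hash for hierarchical sub-streams
hash_id <- function(id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

substream_seed <- function(root_seed, id) {
  bitwXor(as.integer(root_seed) %% 2147483629L, hash_id(id))
}

# branch point estimates, mapping any beta_pert_spec to its mode
point_probs <- function(node) {
  vapply(node$probs, function(p) {
    if (is.numeric(p)) as.numeric(p)
    else if (inherits(p, "beta_pert_spec")) p$mode
    else stop(sprintf("unresolved parameter in node '%s'", node$node_id),
              call. = FALSE)
  }, numeric(1))
}

# classify every chance node for PSA redraw; returns list of
# list(node_id, family, spec/probs, k)
collect_psa_params <- function(tree, alpha_scale = 100) {
  params <- list()
  walk <- function(node) {
    if (is_terminal(node)) return(invisible(NULL))
    k <- length(node$children)
    p <- point_probs(node)
    entry <- NULL
    if (identical(node$dist, "fixed") || any(p <= 0) || any(p >= 1)) {
      entry <- list(node_id = node$node_id, family = "fixed", probs = p)
    } else if (inherits(node$dist, "dirichlet_spec")) {
      entry <- list(node_id = node$node_id, family = "dirichlet",
                    spec = node$dist, probs = p)
    } else if (k == 2) {
      spec <- if (inherits(node$probs[[1]], "beta_pert_spec")) {
        node$probs[[1]]
      } else {
        beta_pert_spec(p[1])
      }
      entry <- list(node_id = node$node_id, family = "pert", spec = spec,
                    probs = p)
    } else {
      entry <- list(node_id = node$node_id, family = "dirichlet",
                    spec = dirichlet_spec(p * alpha_scale), probs = p)
    }
    params[[node$node_id]] <<- entry
    lapply(node$children, walk)
    invisible(NULL)
  }
  walk(tree$root)
  params
}

# symbolic path table: per path, edge list (node_id, branch) + terminal
symbolic_paths <- function(tree) {
  paths <- list()
  walk <- function(node, edges) {
    if (is_terminal(node)) {
      paths[[length(paths) + 1L]] <<- list(edges = edges, terminal = node)
      return(invisible(NULL))
    }
    for (i in seq_along(node$children)) {
      walk(node$children[[i]], c(edges, list(c(node$node_id, i))))
    }
  }
  walk(tree$root, list())
  paths
}

#' Run a multi-way probabilistic sensitivity analysis
#'
#' Per run, all uncertain parameters are redrawn jointly and independently —
#' every nonzero cost-table cell from its Gamma distribution (SD = 20% of the
#' mean by default), every two-branch probability from its Beta-PERT, every
#' k>=3-branch node from its Dirichlet — the tree is evaluated
#' deterministically and scaled by incidence. Degenerate (0/1) and
#' explicitly fixed nodes are not redrawn.
#'
#' @param tree A resolved [decision_tree()]. Terminals carrying a procedure
#'   schedule get their costs recomputed from the redrawn cost matrix;
#'   terminals without a schedule keep their fixed costs.
#' @param cost_matrix Procedures x payers cost matrix (thousand LBP) whose
#'   nonzero cells receive Gamma uncertainty; `NULL` keeps all terminal
#'   costs fixed.
#' @param incidence Yearly incidence used to scale per-patient costs to
#'   national annual costs (default 1 = per-patient).
#' @param config A [psa_config()].
#' @param cost_sd_frac Gamma SD as a fraction of the mean (default 0.2).
#' @param prob_uncertainty If `FALSE`, freeze all branch probabilities at
#'   their point estimates (costs may still vary); with `cost_matrix = NULL`
#'   as well, every run is identical — the degenerate limit.
#' @return An object of class `psa_result`: `draws` (n_runs x 4 matrix:
#'   `tpp`, `oop`, `bdl`, `total`, thousand LBP), `mean`, `ci`, `min`,
#'   `max`, plus the configuration used.
#' @export
run_psa <- function(tree, cost_matrix = NULL, incidence = 1,
                    config = psa_config(), cost_sd_frac = 0.2,
                    prob_uncertainty = TRUE) {
  validate_tree(tree)
  n <- config$n_runs
  if (!is.null(config$ci_level) && n < 2) {
    stop("confidence intervals need at least 2 runs", call. = FALSE)
  }

  # collect PSA families before resolving so explicit branch specs are kept
  params <- collect_psa_params(tree, alpha_scale = config$alpha_scale)
  if (!prob_uncertainty) {
    params <- lapply(params, function(pm) {
      list(node_id = pm$node_id, family = "fixed", probs = pm$probs)
    })
  }
  if (!tree_resolved(tree)) tree <- resolve_tree(tree)
  paths <- symbolic_paths(tree)
  n_paths <- length(paths)

  # draw branch probabilities: one n x k matrix per chance node
  prob_draws <- lapply(params, function(pm) {
    if (pm$family == "fixed") {
      matrix(pm$probs, nrow = n, ncol = length(pm$probs), byrow = TRUE)
    } else if (pm$family == "pert") {
      set.seed(substream_seed(config$seed, paste0("prob:", pm$node_id)))
      p <- sample_beta_pert(pm$spec, n)
      cbind(p, 1 - p, deparse.level = 0)
    } else {
      set.seed(substream_seed(config$seed, paste0("prob:", pm$node_id)))
      sample_dirichlet(pm$spec, n)
    }
  })

  # draw cost-table cells: one n x n_proc matrix per payer
  cost_draws <- NULL
  if (!is.null(cost_matrix)) {
    cost_draws <- lapply(payer_names, function(payer) {
      m <- matrix(0, n, nrow(cost_matrix),
                  dimnames = list(NULL, rownames(cost_matrix)))
      for (proc in rownames(cost_matrix)) {
        mu <- cost_matrix[proc, payer]
        if (mu > 0) {
          set.seed(substream_seed(config$seed,
                                  paste0("cost:", proc, ":", payer)))
          m[, proc] <- sample_gamma(gamma_spec(mu, cost_sd_frac * mu), n)
        }
      }
      m
    })
    names(cost_draws) <- payer_names
  }

  # path probabilities per run
  P <- matrix(1, n, n_paths)
  for (j in seq_len(n_paths)) {
    for (edge in paths[[j]]$edges) {
      P[, j] <- P[, j] * prob_draws[[edge[1]]][, as.integer(edge[2])]
    }
  }

  # terminal 5-year cost per payer per run
  term_cost <- function(payer) {
    vapply(paths, function(pt) {
      term <- pt$terminal
      if (!is.null(cost_draws) && !is.null(term$schedule)) {
        tot <- rowSums(term$schedule)
        as.numeric(cost_draws[[payer]][, names(tot), drop = FALSE] %*% tot)
      } else {
        rep(sum(term$per_year_costs[, payer]), n)
      }
    }, numeric(n))
  }

  draws <- matrix(0, n, 4, dimnames = list(NULL, c(payer_names, "total")))
  for (payer in payer_names) {
    draws[, payer] <- rowSums(P * term_cost(payer)) * incidence
  }
  draws[, "total"] <- rowSums(draws[, payer_names])

  means <- colMeans(draws)
  ci <- NULL
  if (!is.null(config$ci_level)) {
    a <- (1 - config$ci_level) / 2
    ci <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    rownames(ci) <- c("lower", "upper")
  }
  structure(
    list(draws = draws, mean = means, ci = ci,
         min = apply(draws, 2, min), max = apply(draws, 2, max),
         incidence = incidence, config = config, model = tree$name),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s: %d runs, incidence %g\n", x$model,
              nrow(x$draws), x$incidence))
  print(psa_summary(x))
  invisible(x)
}

#' Summarize a PSA result
#'
#' One row per payer plus the total: Monte Carlo mean, percentile confidence
#' interval, simulated min/max, and the payer's share of the total mean cost
#' (raw and display-rounded to integer percent).
#'
#' @param result A `psa_result`.
#' @return A data frame with columns `payer`, `mean`, `ci_low`, `ci_high`,
#'   `min`, `max`, `share_raw`, `share_pct`.
#' @export
psa_summary <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  total_mean <- result$mean[["total"]]
  if (total_mean == 0) {
    stop("total mean cost is zero: payer shares are undefined", call. = FALSE)
  }
  rows <- c(payer_names, "total")
  share_raw <- 100 * result$mean[rows] / total_mean
  data.frame(
    payer = toupper(rows),
    mean = unname(result$mean[rows]),
    ci_low = if (is.null(result$ci)) NA_real_ else unname(result$ci["lower", rows]),
    ci_high = if (is.null(result$ci)) NA_real_ else unname(result$ci["upper", rows]),
    min = unname(result$min[rows]),
    max = unname(result$max[rows]),
    share_raw = unname(share_raw),
    share_pct = round_half_away(unname(share_raw)),
    stringsAsFactors = FALSE
  )
}
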