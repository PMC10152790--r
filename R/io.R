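# Configuration and report serialization. Models round-trip through a
# versioned YAML layout documented in inst/extdata/model-config-schema.md.

config_schema_version <- "1.0"

node_to_list <- function(node) {
  if (is_terminal(node)) {
    out <- list(
      terminal = node$pathway_id,
      is_death = node$is_death,
      per_year_costs = lapply(seq_len(5), function(i) {
        as.list(node$per_year_costs[i, ])
      })
    )
    if (!is.null(node$stage)) out$stage <- node$stage
    if (!is.null(node$schedule)) {
      out$schedule <- lapply(rownames(node$schedule), function(p) {
        list(procedure = p, counts = as.numeric(node$schedule[p, ]))
      })
    }
    return(out)
  }
  branches <- lapply(seq_along(node$children), function(i) {
    p <- node$probs[[i]]
    b <- if (inherits(p, "beta_pert_spec")) {
      list(prob = list(family = "beta_pert", mode = p$mode, min = p$min,
                       max = p$max, shape = p$shape))
    } else {
      list(prob = p)
    }
    b$child <- node_to_list(node$children[[i]])
    b
  })
  out <- list(node = node$node_id, branches = branches)
  if (inherits(node$dist, "dirichlet_spec")) {
    out$dist <- list(family = "dirichlet", alphas = node$dist$alphas)
  } else if (!identical(node$dist, "auto")) {
    out$dist <- node$dist
  }
  out
}

list_to_node <- function(x) {
  if (!is.null(x$terminal)) {
    costs <- do.call(rbind, lapply(x$per_year_costs, function(y) {
      c(tpp = y$tpp, oop = y$oop, bdl = y$bdl)
    }))
    schedule <- NULL
    if (!is.null(x$schedule)) {
      schedule <- do.call(rbind, lapply(x$schedule, function(s) {
        as.numeric(s$counts)
      }))
      rownames(schedule) <- vapply(x$schedule, `[[`, character(1),
                                   "procedure")
    }
    return(terminal_node(x$terminal, per_year_costs = costs,
                         is_death = isTRUE(x$is_death),
                         schedule = schedule, stage = x$stage))
  }
  if (is.null(x$node) || is.null(x$branches)) {
    stop("config node is neither a terminal nor a chance node", call. = FALSE)
  }
  probs <- lapply(x$branches, function(b) {
    p <- b$prob
    if (is.list(p)) {
      if (!identical(p$family, "beta_pert")) {
        stop(sprintf("node '%s': unknown probability family '%s'",
                     x$node, p$family), call. = FALSE)
      }
      beta_pert_spec(p$mode, p$min, p$max, p$shape)
    } else {
      as.numeric(p)
    }
  })
  dist <- if (is.null(x$dist)) {
    "auto"
  } else if (is.list(x$dist)) {
    dirichlet_spec(as.numeric(x$dist$alphas))
  } else {
    x$dist
  }
  chance_node(x$node,
              children = lapply(x$branches, function(b) list_to_node(b$child)),
              probs = probs, dist = dist)
}

#' Write a model configuration file
#'
#' Serializes a decision tree (with optional cost table and scenario
#' metadata) to the package's YAML configuration layout. A read-back of the
#' written file reconstructs a semantically identical model.
#'
#' @param model A list with `tree` (a [decision_tree()]) and optionally
#'   `cost_table` (a [cost_table()]) and `scenario` (a [scenario_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  if (inherits(model, "decision_tree")) model <- list(tree = model)
  cfg <- list(schema_version = config_schema_version,
              name = model$tree$name,
              tree = node_to_list(model$tree$root))
  if (!is.null(model$cost_table)) {
    cfg$cost_table <- lapply(seq_len(nrow(model$cost_table)), function(i) {
      as.list(model$cost_table[i, setdiff(names(model$cost_table),
                                          "pre_bdl")])
    })
  }
  if (!is.null(model$scenario)) {
    s <- model$scenario
    cfg$scenario <- list(label = s$label, epoch = s$epoch,
                         exchange_rate = s$exchange_rate,
                         incidence = s$incidence,
                         zero_subsidy = s$zero_subsidy)
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read and validate a model configuration file
#'
#' Rebuilds the decision tree (validating all structural invariants: unique
#' ids, branch arity, probability sums) plus any cost table and scenario
#' metadata.
#'
#' @param path Path to a YAML model configuration.
#' @return A list with `tree` and, when present in the file, `cost_table`
#'   and `scenario`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tree)) stop("config has no 'tree' section", call. = FALSE)
  tree <- decision_tree(list_to_node(cfg$tree),
                        name = if (is.null(cfg$name)) "model" else cfg$name)
  out <- list(tree = tree)
  if (!is.null(cfg$cost_table)) {
    rows <- cfg$cost_table
    out$cost_table <- cost_table(
      procedure_id = vapply(rows, `[[`, character(1), "procedure_id"),
      label = vapply(rows, `[[`, character(1), "label"),
      pre_tpp = vapply(rows, `[[`, numeric(1), "pre_tpp"),
      pre_oop = vapply(rows, `[[`, numeric(1), "pre_oop"),
      post_tpp = vapply(rows, `[[`, numeric(1), "post_tpp"),
      post_oop = vapply(rows, `[[`, numeric(1), "post_oop"),
      post_bdl = vapply(rows, `[[`, numeric(1), "post_bdl")
    )
  }
  if (!is.null(cfg$scenario)) {
    s <- cfg$scenario
    out$scenario <- scenario_config(label = s$label, epoch = s$epoch,
                                    exchange_rate = s$exchange_rate,
                                    incidence = s$incidence,
                                    zero_subsidy = isTRUE(s$zero_subsidy))
  }
  out
}

#' Write a scenario report as delimited text
#'
#' One row per payer per scenario: mean, percentile CI, simulated min/max,
#' share of total, and USD conversions. Full-precision columns sit alongside
#' the display-rounded ones, so a reader can re-derive every printed number.
#'
#' @param results A named list of `scenario_result` objects.
#' @param path Output file (tab-separated).
#' @return The assembled data frame, invisibly.
#' @export
write_report <- function(results, path) {
  if (!length(results)) stop("no results to report", call. = FALSE)
  missing_summ <- names(results)[!vapply(results, function(r) {
    inherits(r, "scenario_result")
  }, logical(1))]
  if (length(missing_summ)) {
    stop(sprintf("incomplete results for scenarios: %s",
                 paste(missing_summ, collapse = ", ")), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    s <- s[s$mean > 0 | s$payer == "TOTAL", ]
    cbind(scenario = nm, s)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a result file bitwise with the
#' same build: seed, run count, scenario labels, package version, timestamp.
#'
#' @param path Manifest file path (YAML).
#' @param seed,n_runs PSA settings used.
#' @param scenarios Character vector of scenario labels.
#' @param outputs Character vector of files the run produced.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, n_runs, scenarios,
                           outputs = character()) {
  yaml::write_yaml(list(
    seed = as.integer(seed), n_runs = as.integer(n_runs),
    scenarios = as.list(scenarios),
    package_version = as.character(utils::packageVersion("bccost")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  ), path)
  invisible(path)
}

#' Run the full analysis suite
#'
#' Executes the realistic pre- and post-collapse scenarios plus the
#' zero-subsidy and pre-collapse full-adherence counterfactuals, and derives
#' the comparison battery: USD conversions, percent changes (total, TPP,
#' OOP), payer shares, diagnosis-gate statistics, per-stage cost shares and
#' overall mortality per epoch.
#'
#' @param seed Root PSA seed.
#' @param n_runs Monte Carlo runs per scenario.
#' @param out_dir Optional directory for report/manifest files; `NULL` skips
#'   writing.
#' @return A list: `scenarios` (named `scenario_result`s), `comparisons`
#'   (named [compare_scenarios()] reports), `derived` (named scalar
#'   statistics), `stage_breakdown` (per epoch).
#' @export
run_analysis_suite <- function(seed = 1, n_runs = 20000, out_dir = NULL) {
  cfg <- psa_config(n_runs = n_runs, seed = seed)
  labels <- c("pre_collapse", "post_collapse", "post_collapse_zero_subsidy",
              "full_adherence_pre")
  scenarios <- lapply(labels, run_scenario, config = cfg)
  names(scenarios) <- labels

  comparisons <- list(
    post_vs_pre = compare_scenarios(scenarios$pre_collapse,
                                    scenarios$post_collapse),
    zero_subsidy_vs_post = compare_scenarios(scenarios$post_collapse,
                                             scenarios$post_collapse_zero_subsidy),
    full_adherence_vs_pre = compare_scenarios(scenarios$pre_collapse,
                                              scenarios$full_adherence_pre)
  )

  mean_of <- function(label, payer) {
    s <- scenarios[[label]]$summary
    s$mean[s$payer == toupper(payer)]
  }
  gate_pre <- diagnosis_gate_stats(bc_adherence("pre"))
  gate_post <- diagnosis_gate_stats(bc_adherence("post"))
  consts <- bc_constants()
  derived <- list(
    total_pre_usd = convert_to_usd(mean_of("pre_collapse", "total"),
                                   consts$rate_pre),
    total_post_usd = convert_to_usd(mean_of("post_collapse", "total"),
                                    consts$rate_post),
    pct_change_total = percent_change(mean_of("pre_collapse", "total"),
                                      mean_of("post_collapse", "total")),
    pct_change_tpp = percent_change(mean_of("pre_collapse", "tpp"),
                                    mean_of("post_collapse", "tpp")),
    pct_change_oop = percent_change(mean_of("pre_collapse", "oop"),
                                    mean_of("post_collapse", "oop")),
    share_health_expenditure =
      share_of_health_expenditure(mean_of("pre_collapse", "total"),
                                  consts$health_expenditure_2017),
    gate_never_return_pre = gate_pre[["never_return"]],
    gate_never_return_post = gate_post[["never_return"]],
    gate_late_care_pre = gate_pre[["late_care"]],
    gate_late_care_post = gate_post[["late_care"]],
    mortality_pre = scenarios$pre_collapse$mortality,
    mortality_post = scenarios$post_collapse$mortality
  )

  breakdown <- lapply(c(pre = "pre_collapse", post = "post_collapse"),
                      function(lbl) {
    model <- build_bc_model(scenarios[[lbl]]$scenario)
    sc <- stage_costs(model$tree)
    stage_cost_breakdown(sc[sc$stage != "(untagged)", ])
  })

  out <- list(scenarios = scenarios, comparisons = comparisons,
              derived = derived, stage_breakdown = breakdown)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- file.path(out_dir, "scenario-report.tsv")
    write_report(scenarios, report)
    write_manifest(file.path(out_dir, "manifest.yaml"), seed = seed,
                   n_runs = n_runs, scenarios = labels, outputs = report)
  }
  out
}
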