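#' Display rounding: half away from zero
#'
#' The single rounding routine used for every printed percentage (base R's
#' `round()` rounds half to even, which is not how report tables are
#' rounded).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return `x` rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Convert thousand LBP to USD
#'
#' @param amount_thousand_lbp Amount in thousand LBP.
#' @param exchange_rate LBP per USD (1,500 pre-collapse, 23,000
#'   post-collapse).
#' @param display If `TRUE` (default), truncate toward zero to whole USD as
#'   in report tables; if `FALSE`, return full precision.
#' @return USD amount.
#' @export
convert_to_usd <- function(amount_thousand_lbp, exchange_rate,
                           display = TRUE) {
  if (!is.numeric(exchange_rate) || exchange_rate <= 0) {
    stop("exchange rate must be positive", call. = FALSE)
  }
  usd <- amount_thousand_lbp * 1000 / exchange_rate
  if (display) trunc(usd) else usd
}

#' Percent change between two amounts
#'
#' @param before Baseline amount (> 0).
#' @param after New amount.
#' @return `100 * (after - before) / before`, full precision. Apply
#'   [round_half_away()] for display.
#' @export
percent_change <- function(before, after) {
  if (!is.numeric(before) || any(before <= 0)) {
    stop("percent change needs a positive baseline", call. = FALSE)
  }
  100 * (after - before) / before
}

#' Zero-subsidy counterfactual transform
#'
#' Models the extreme scenario in which the central bank stops all drug
#' subsidies: every post-collapse BDL amount is reassigned to households
#' (OOP), TPP amounts are untouched, and each procedure's three-way total is
#' conserved. Only meaningful in the post-collapse epoch (no subsidies exist
#' pre-collapse).
#'
#' @param table A [cost_table()].
#' @param epoch Must be `"post"`.
#' @return The transformed `cost_table` (all `post_bdl` zero).
#' @export
apply_zero_subsidy <- function(table, epoch = "post") {
  if (!identical(epoch, "post")) {
    stop("zero-subsidy applies only to the post-collapse epoch (no subsidies exist pre-collapse)",
         call. = FALSE)
  }
  table$post_oop <- table$post_oop + table$post_bdl
  table$post_bdl <- 0
  table
}

#' Full-adherence counterfactual transform
#'
#' Sets every stage's optimal proportion to 1 (sub-optimal and no-follow-up
#' to 0) and forces the diagnosis gate to timely TURBT. Idempotent.
#'
#' @param adherence An adherence list as returned by [bc_adherence()].
#' @return The modified adherence list.
#' @export
apply_full_adherence <- function(adherence) {
  adherence$gate[c("turbt", "nothing")] <- c(1, 0)
  adherence$stages$optimal <- 1
  adherence$stages$suboptimal <- 0
  adherence$stages$none <- 0
  adherence
}

#' Disease cost as a share of total health expenditure
#'
#' @param annual_cost_thousand_lbp Annual disease cost, thousand LBP.
#' @param total_health_exp_thousand_lbp Total national health expenditure,
#'   thousand LBP (> 0).
#' @return Percent share, display-rounded to 2 decimals.
#' @export
share_of_health_expenditure <- function(annual_cost_thousand_lbp,
                                        total_health_exp_thousand_lbp) {
  if (!is.numeric(total_health_exp_thousand_lbp) ||
      total_health_exp_thousand_lbp <= 0) {
    stop("total health expenditure must be positive", call. = FALSE)
  }
  round_half_away(
    100 * annual_cost_thousand_lbp / total_health_exp_thousand_lbp,
    digits = 2
  )
}

#' Diagnosis-gate statistics
#'
#' Two headline products of the diagnosis gate: the fraction of diagnosed
#' patients who never receive care (do nothing x never come back) and the
#' fraction seeking care late (do nothing x late TURBT).
#'
#' @param adherence An adherence list as returned by [bc_adherence()].
#' @return `c(never_return = , late_care = )`, fractions.
#' @export
diagnosis_gate_stats <- function(adherence) {
  g <- adherence$gate
  c(never_return = unname(g[["nothing"]] * g[["never_back"]]),
    late_care = unname(g[["nothing"]] * g[["late_turbt"]]))
}

#' Per-stage share of total expected cost
#'
#' @param per_stage_costs A data frame as returned by [stage_costs()] (or any
#'   data frame with `stage` and `total` columns).
#' @return The input with `share_raw` (percent, exact) and `share_pct`
#'   (display-rounded integer percent) columns; raw shares sum to 100.
#' @export
stage_cost_breakdown <- function(per_stage_costs) {
  tot <- sum(per_stage_costs$total)
  if (tot == 0) stop("total cost is zero: shares undefined", call. = FALSE)
  per_stage_costs$share_raw <- 100 * per_stage_costs$total / tot
  per_stage_costs$share_pct <- round_half_away(per_stage_costs$share_raw)
  per_stage_costs
}

#' Scenario configuration
#'
#' Bundles everything needed to run one analysis scenario: the price epoch,
#' the exchange rate for USD reporting, the yearly incidence, the adherence
#' table, and the counterfactual toggles.
#'
#' @param label One of `"pre_collapse"`, `"post_collapse"`,
#'   `"post_collapse_zero_subsidy"`, `"full_adherence_pre"`, or a custom
#'   label (then `epoch`, `exchange_rate` etc. must be supplied).
#' @param epoch Price epoch, `"pre"` or `"post"`.
#' @param exchange_rate LBP per USD.
#' @param incidence New cases per year (default 781).
#' @param adherence Adherence list; defaults to [bc_adherence()] for the
#'   epoch, with [apply_full_adherence()] applied for the full-adherence
#'   scenario.
#' @param zero_subsidy Reassign all BDL subsidies to OOP before evaluation.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(label = "pre_collapse", epoch = NULL,
                            exchange_rate = NULL, incidence = 781,
                            adherence = NULL, zero_subsidy = FALSE) {
  defaults <- list(
    pre_collapse = list(epoch = "pre", rate = 1500, zero = FALSE,
                        full = FALSE),
    post_collapse = list(epoch = "post", rate = 23000, zero = FALSE,
                         full = FALSE),
    post_collapse_zero_subsidy = list(epoch = "post", rate = 23000,
                                      zero = TRUE, full = FALSE),
    full_adherence_pre = list(epoch = "pre", rate = 1500, zero = FALSE,
                              full = TRUE)
  )
  d <- defaults[[label]]
  if (!is.null(d)) {
    if (is.null(epoch)) epoch <- d$epoch
    if (is.null(exchange_rate)) exchange_rate <- d$rate
    if (missing(zero_subsidy)) zero_subsidy <- d$zero
    if (is.null(adherence)) {
      adherence <- bc_adherence(epoch)
      if (d$full) adherence <- apply_full_adherence(adherence)
    }
  }
  if (is.null(epoch) || is.null(exchange_rate)) {
    stop("custom scenarios need explicit epoch and exchange_rate",
         call. = FALSE)
  }
  if (exchange_rate <= 0) stop("exchange rate must be positive",
                               call. = FALSE)
  if (is.null(adherence)) adherence <- bc_adherence(epoch)
  sums <- adherence$stages$optimal + adherence$stages$suboptimal +
    adherence$stages$none
  if (any(abs(sums - 1) > 1e-9)) {
    stop("adherence rows must each sum to 1", call. = FALSE)
  }
  structure(list(label = label, epoch = epoch,
                 exchange_rate = exchange_rate, incidence = incidence,
                 adherence = adherence, zero_subsidy = zero_subsidy),
            class = "scenario_config")
}

#' Build the model instance for a scenario
#'
#' @param scenario A [scenario_config()].
#' @return A list with `tree`, `cost_matrix` (after any zero-subsidy
#'   transform) and `scenario`.
#' @export
build_bc_model <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  tab <- bc_cost_table()
  if (scenario$zero_subsidy) tab <- apply_zero_subsidy(tab, scenario$epoch)
  cm <- epoch_costs(tab, scenario$epoch)
  tree <- build_bc_fixture(scenario$epoch, adherence = scenario$adherence,
                           cost_matrix = cm)
  list(tree = tree, cost_matrix = cm, scenario = scenario)
}

#' Run one scenario end to end
#'
#' Builds the scenario model, runs the PSA at national scale, and returns
#' the summary alongside deterministic quantities.
#'
#' @param scenario A [scenario_config()] or a scenario label.
#' @param config A [psa_config()].
#' @return A list of class `scenario_result`: `scenario`, `psa`
#'   (a `psa_result`), `summary` (with USD columns), `deterministic`
#'   (expected national annual cost, no uncertainty), `mortality`.
#' @export
run_scenario <- function(scenario, config = psa_config()) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  model <- build_bc_model(scenario)
  psa <- run_psa(model$tree, cost_matrix = model$cost_matrix,
                 incidence = scenario$incidence, config = config)
  summ <- psa_summary(psa)
  summ$mean_usd <- convert_to_usd(summ$mean, scenario$exchange_rate)
  summ$ci_low_usd <- convert_to_usd(summ$ci_low, scenario$exchange_rate)
  summ$ci_high_usd <- convert_to_usd(summ$ci_high, scenario$exchange_rate)
  det <- annual_national_cost(scenario$incidence, expected_cost(model$tree))
  structure(list(scenario = scenario, psa = psa, summary = summ,
                 deterministic = det,
                 mortality = mortality_rate(model$tree)),
            class = "scenario_result")
}

#' Compare two scenario results
#'
#' Per-payer absolute differences (thousand LBP) and percent changes of the
#' PSA mean costs, plus the total percent change — the comparison statistics
#' printed alongside counterfactual runs.
#'
#' @param baseline,alternative `scenario_result` objects.
#' @return A data frame of class `comparison_report` with `payer`,
#'   `mean_baseline`, `mean_alternative`, `difference`, `pct_change_raw`,
#'   `pct_change` (display-rounded).
#' @export
compare_scenarios <- function(baseline, alternative) {
  stopifnot(inherits(baseline, "scenario_result"),
            inherits(alternative, "scenario_result"))
  b <- baseline$summary
  a <- alternative$summary
  stopifnot(identical(b$payer, a$payer))
  diff <- a$mean - b$mean
  pct <- ifelse(b$mean > 0, 100 * diff / b$mean, NA_real_)
  out <- data.frame(payer = b$payer, mean_baseline = b$mean,
                    mean_alternative = a$mean, difference = diff,
                    pct_change_raw = pct,
                    pct_change = round_half_away(pct),
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_report", "data.frame")
  out
}
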