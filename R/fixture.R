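# Packaged Lebanon bladder-cancer model instance.
#
# The published pathway model is hosted online and too large to print; this
# fixture rebuilds its stated structure from the packaged tables plus
# documented guideline-flavoured pathway templates: a diagnosis gate (timely
# vs late vs never TURBT), six risk groups (low / intermediate / high /
# very-high non-muscle-invasive, muscle-invasive, metastatic), each with
# optimal / sub-optimal / no-follow-up arms, per-year procedure schedules
# over the 5-year horizon, and terminal death indicators. Schedules and
# death probabilities are explicit fixture approximations (see the methods
# vignette), not the original authors' values.

fixture_stage_names <- c("low", "intermediate", "high", "very_high",
                         "invasive", "metastatic")

# stage mix at diagnosis; timely vs late (stage shift when TURBT is delayed)
fixture_stage_mix <- function(timing = c("timely", "late")) {
  timing <- match.arg(timing)
  mix <- switch(timing,
    timely = c(0.25, 0.25, 0.15, 0.10, 0.20, 0.05),
    late   = c(0.08, 0.17, 0.15, 0.15, 0.30, 0.15)
  )
  names(mix) <- fixture_stage_names
  mix
}

# 5-year death probability per stage and follow-up arm (fixture calibration
# parameters, held fixed during PSA)
fixture_death_probs <- function() {
  list(
    low          = c(optimal = 0.010, suboptimal = 0.020, none = 0.050),
    intermediate = c(optimal = 0.030, suboptimal = 0.050, none = 0.100),
    high         = c(optimal = 0.080, suboptimal = 0.120, none = 0.250),
    very_high    = c(optimal = 0.120, suboptimal = 0.180, none = 0.350),
    invasive     = c(optimal = 0.280, suboptimal = 0.380, none = 0.620),
    metastatic   = c(optimal = 0.760, suboptimal = NA,    none = 0.880),
    never_back   = 0.400
  )
}

# merge named count vectors by name (base `+` aligns by position, not name)
counts <- function(...) {
  parts <- list(...)
  ids <- unique(unlist(lapply(parts, names)))
  out <- stats::setNames(numeric(length(ids)), ids)
  for (p in parts) out[names(p)] <- out[names(p)] + p
  out
}

# build a procedures x 5 schedule matrix from per-year named count vectors
sched <- function(y1 = NULL, y2 = NULL, y3 = NULL, y4 = NULL, y5 = NULL) {
  years <- list(y1, y2, y3, y4, y5)
  ids <- unique(unlist(lapply(years, names)))
  m <- matrix(0, length(ids), 5, dimnames = list(ids, paste0("y", 1:5)))
  for (j in 1:5) {
    y <- years[[j]]
    if (length(y)) m[names(y), j] <- m[names(y), j] + y
  }
  m
}

# year-1 diagnostic workup shared by every pathway that reaches TURBT
workup <- c(consult = 2, urinalysis = 2, urine_culture = 1, pelvic_us = 1,
            ct_urogram = 1, cystoscopy = 1, turbt = 1)

# expected procedure counts per follow-up year for every stage x arm;
# optimal arms follow EAU-style surveillance, sub-optimal arms thin it out,
# no-follow-up arms stop after the diagnostic workup
fixture_schedules <- function() {
  fu <- function(x) c(cystoscopy = x, consult = x, urinalysis = x)
  list(
    low = list(
      optimal = sched(
        y1 = counts(workup, c(mmc = 1), fu(1)),
        y2 = fu(1), y3 = fu(1), y4 = fu(1), y5 = fu(1)
      ),
      suboptimal = sched(
        y1 = counts(workup, c(mmc = 1)),
        y2 = fu(0.4), y3 = fu(0.4), y4 = fu(0.4), y5 = fu(0.4)
      ),
      none = sched(y1 = workup)
    ),
    intermediate = list(
      optimal = sched(
        y1 = counts(workup, c(mmc = 6), fu(3)),
        y2 = counts(c(mmc = 3), fu(2)), y3 = fu(1), y4 = fu(1), y5 = fu(1)
      ),
      suboptimal = sched(
        y1 = counts(workup, c(mmc = 3, cystoscopy = 1, consult = 1)),
        y2 = fu(1), y3 = fu(0.5), y4 = fu(0.5), y5 = fu(0.5)
      ),
      none = sched(y1 = workup)
    ),
    high = list(
      optimal = sched(
        y1 = counts(workup, c(turbt = 1, bcg = 9, ct_urogram = 1), fu(3)),
        y2 = counts(c(bcg = 6, ct_urogram = 1, cystectomy = 0.05), fu(4)),
        y3 = counts(c(bcg = 3, ct_urogram = 1), fu(2)),
        y4 = counts(c(ct_urogram = 1), fu(2)),
        y5 = counts(c(ct_urogram = 1), fu(2))
      ),
      suboptimal = sched(
        y1 = counts(workup, c(bcg = 6, cystoscopy = 1, consult = 1)),
        y2 = counts(c(cystectomy = 0.12), fu(2)),
        y3 = fu(1), y4 = fu(1), y5 = fu(1)
      ),
      none = sched(y1 = workup, y2 = c(consult = 0.5),
                   y3 = c(palliative_rt = 0.2, consult = 0.5))
    ),
    very_high = list(
      optimal = sched(
        y1 = counts(workup, c(turbt = 1, bcg = 9, ct_urogram = 1,
                              tap_scan = 1), fu(3)),
        y2 = counts(c(bcg = 6, ct_urogram = 1, cystectomy = 0.15), fu(4)),
        y3 = counts(c(bcg = 3, ct_urogram = 1), fu(2)),
        y4 = counts(c(ct_urogram = 1), fu(2)),
        y5 = counts(c(ct_urogram = 1), fu(2))
      ),
      suboptimal = sched(
        y1 = counts(workup, c(bcg = 6, cystoscopy = 1, consult = 1,
                              tap_scan = 0.5)),
        y2 = counts(c(cystectomy = 0.15), fu(2)),
        y3 = fu(1), y4 = fu(1), y5 = fu(1)
      ),
      none = sched(y1 = workup, y2 = c(palliative_rt = 0.2, consult = 0.5),
                   y3 = c(consult = 0.5))
    ),
    invasive = list(
      optimal_nac_rc = sched(
        y1 = counts(workup, c(consult = 4, tap_scan = 2, ddmvac = 1,
                              cystectomy = 1)),
        y2 = c(tap_scan = 2, consult = 2, urinalysis = 1),
        y3 = c(tap_scan = 1, consult = 1), y4 = c(tap_scan = 1, consult = 1),
        y5 = c(tap_scan = 1, consult = 1)
      ),
      optimal_tmt = sched(
        y1 = counts(workup, c(consult = 4, tap_scan = 2, tmt = 1)),
        y2 = c(cystoscopy = 2, tap_scan = 2, consult = 2),
        y3 = c(cystoscopy = 1, tap_scan = 1, consult = 1),
        y4 = c(cystoscopy = 1, tap_scan = 1, consult = 1),
        y5 = c(cystoscopy = 1, tap_scan = 1, consult = 1)
      ),
      suboptimal = sched(
        y1 = counts(workup, c(consult = 2, tap_scan = 1, cystectomy = 1)),
        y2 = c(tap_scan = 1, consult = 1),
        y3 = c(tap_scan = 0.5, consult = 0.5),
        y4 = c(tap_scan = 0.5, consult = 0.5),
        y5 = c(tap_scan = 0.5, consult = 0.5)
      ),
      none = sched(y1 = workup, y2 = c(palliative_rt = 0.4, consult = 1),
                   y3 = c(consult = 0.5))
    ),
    metastatic = list(
      chemo_1l = sched(
        y1 = counts(workup, c(consult = 4, tap_scan = 2, gem_cis = 0.6,
                              gem_carbo = 0.4)),
        y2 = c(immuno_2l = 0.25, tap_scan = 2, consult = 3,
               palliative_rt = 0.2),
        y3 = c(tap_scan = 1, consult = 2), y4 = c(tap_scan = 1, consult = 2),
        y5 = c(tap_scan = 1, consult = 2)
      ),
      immuno_1l = sched(
        y1 = counts(workup, c(consult = 4, tap_scan = 2, immuno_1l = 1)),
        y2 = c(tap_scan = 2, consult = 3, palliative_rt = 0.2),
        y3 = c(tap_scan = 1, consult = 2), y4 = c(tap_scan = 1, consult = 2),
        y5 = c(tap_scan = 1, consult = 2)
      ),
      none = sched(y1 = counts(workup, c(consult = 1, palliative_rt = 0.5)),
                   y2 = c(consult = 1, palliative_rt = 0.3))
    ),
    never_back = sched(y1 = c(consult = 1, urinalysis = 1, pelvic_us = 1))
  )
}

# fold a schedule into a 5 x 3 per-year payer cost matrix
fold_schedule <- function(schedule, cost_matrix) {
  ids <- rownames(schedule)
  missing <- setdiff(ids, rownames(cost_matrix))
  if (length(missing)) {
    stop(sprintf("schedule references unknown procedures: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  t(schedule) %*% cost_matrix[ids, , drop = FALSE]
}

# an arm ends in a fixed death-vs-survival split; both terminals carry the
# arm's schedule (costs accrue along the pathway whether or not it ends in
# death within the horizon)
arm_node <- function(id, schedule, death_prob, cost_matrix, stage) {
  costs <- fold_schedule(schedule, cost_matrix)
  mk <- function(suffix, death) {
    terminal_node(paste0(id, ".", suffix), per_year_costs = costs,
                  is_death = death, schedule = schedule, stage = stage)
  }
  if (death_prob <= 0) return(mk("alive", FALSE))
  if (death_prob >= 1) return(mk("death", TRUE))
  chance_node(paste0(id, ".outcome"),
              children = list(mk("death", TRUE), mk("alive", FALSE)),
              probs = c(death_prob, 1 - death_prob),
              dist = "fixed")
}

stage_subtree <- function(prefix, stage, adherence, schedules, deaths,
                          cost_matrix) {
  sc <- schedules[[stage]]
  d <- deaths[[stage]]
  row <- adherence$stages[adherence$stages$stage == stage, ]
  id <- function(...) paste(c(prefix, stage, ...), collapse = ".")
  if (stage == "metastatic") {
    treated <- chance_node(
      id("treated.line"),
      children = list(
        arm_node(id("chemo"), sc$chemo_1l, d[["optimal"]], cost_matrix, stage),
        arm_node(id("immuno"), sc$immuno_1l, d[["optimal"]], cost_matrix,
                 stage)
      ),
      probs = unname(adherence$metastatic_split)
    )
    return(chance_node(
      id("arm"),
      children = list(treated,
                      arm_node(id("none"), sc$none, d[["none"]], cost_matrix,
                               stage)),
      probs = c(row$optimal, row$none)
    ))
  }
  if (stage == "invasive") {
    optimal <- chance_node(
      id("optimal.modality"),
      children = list(
        arm_node(id("nac_rc"), sc$optimal_nac_rc, d[["optimal"]], cost_matrix,
                 stage),
        arm_node(id("tmt"), sc$optimal_tmt, d[["optimal"]], cost_matrix,
                 stage)
      ),
      probs = unname(adherence$invasive_split)
    )
    return(chance_node(
      id("arm"),
      children = list(
        optimal,
        arm_node(id("suboptimal"), sc$suboptimal, d[["suboptimal"]],
                 cost_matrix, stage),
        arm_node(id("none"), sc$none, d[["none"]], cost_matrix, stage)
      ),
      probs = c(row$optimal, row$suboptimal, row$none)
    ))
  }
  chance_node(
    id("arm"),
    children = list(
      arm_node(id("optimal"), sc$optimal, d[["optimal"]], cost_matrix, stage),
      arm_node(id("suboptimal"), sc$suboptimal, d[["suboptimal"]],
               cost_matrix, stage),
      arm_node(id("none"), sc$none, d[["none"]], cost_matrix, stage)
    ),
    probs = c(row$optimal, row$suboptimal, row$none)
  )
}

#' Build the packaged bladder-cancer decision tree
#'
#' Assembles the full pathway model for one scenario: diagnosis gate
#' (timely TURBT / late TURBT / never returns), stage distribution at
#' diagnosis, per-stage follow-up arms with their 5-year procedure
#' schedules, and death-vs-survival terminals.
#'
#' @param epoch `"pre"` or `"post"` price/behaviour epoch.
#' @param adherence Adherence probabilities, default [bc_adherence()] for the
#'   epoch; pass a modified list for counterfactuals.
#' @param cost_matrix Procedures x payers cost matrix, default
#'   [epoch_costs()] of [bc_cost_table()] for the epoch (pass a transformed
#'   matrix, e.g. after [apply_zero_subsidy()], for counterfactuals).
#' @return A [decision_tree()].
#' @export
build_bc_fixture <- function(epoch = c("pre", "post"),
                             adherence = NULL, cost_matrix = NULL) {
  epoch <- match.arg(epoch)
  if (is.null(adherence)) adherence <- bc_adherence(epoch)
  if (is.null(cost_matrix)) cost_matrix <- epoch_costs(bc_cost_table(), epoch)
  schedules <- fixture_schedules()
  deaths <- fixture_death_probs()

  stage_gate <- function(prefix, timing) {
    mix <- fixture_stage_mix(timing)
    chance_node(
      paste0(prefix, ".stage"),
      children = lapply(fixture_stage_names, function(s) {
        stage_subtree(prefix, s, adherence, schedules, deaths, cost_matrix)
      }),
      probs = unname(mix)
    )
  }

  never <- arm_node("never_back", fixture_schedules()$never_back,
                    deaths$never_back, cost_matrix, stage = NULL)
  gate <- adherence$gate
  if (gate[["nothing"]] <= 0) {
    # degenerate gate (e.g. full adherence): everyone reaches timely TURBT,
    # keep a vanishing do-nothing branch out of the tree entirely
    root <- stage_gate("timely", "timely")
    root$node_id <- "diagnosis"
    return(decision_tree(root, name = paste0("bc_lebanon_", epoch)))
  }
  nothing <- chance_node(
    "nothing.return",
    children = list(stage_gate("late", "late"), never),
    probs = unname(gate[c("late_turbt", "never_back")])
  )
  root <- chance_node(
    "diagnosis",
    children = list(stage_gate("timely", "timely"), nothing),
    probs = unname(gate[c("turbt", "nothing")])
  )
  decision_tree(root, name = paste0("bc_lebanon_", epoch))
}

#' Shift adherence mass between follow-up arms
#'
#' Moves probability mass of every stage row toward no-follow-up
#' (`direction = "worse"`) or toward optimal care (`direction = "better"`),
#' preserving row validity. Used to test that cost and mortality respond
#' monotonically to adherence.
#'
#' @param adherence An adherence list as returned by [bc_adherence()].
#' @param direction `"worse"` or `"better"`.
#' @param amount Probability mass to move per stage (default 0.05).
#' @return The perturbed adherence list.
#' @export
perturb_adherence <- function(adherence, direction = c("worse", "better"),
                              amount = 0.05) {
  direction <- match.arg(direction)
  st <- adherence$stages
  from <- if (direction == "worse") "optimal" else "none"
  to <- if (direction == "worse") "none" else "optimal"
  if (any(st[[from]] - amount < -1e-12)) {
    stop(sprintf("shift of %g would make a '%s' probability negative",
                 amount, from), call. = FALSE)
  }
  st[[from]] <- st[[from]] - amount
  st[[to]] <- st[[to]] + amount
  sums <- st$optimal + st$suboptimal + st$none
  stopifnot(all(abs(sums - 1) < 1e-9))
  adherence$stages <- st
  adherence
}

#' Generate a random valid decision tree for property testing
#'
#' Builds a reproducible random tree: branch probabilities come from a
#' stick-breaking scheme (so every node is a valid probability vector),
#' terminals get random 5-year schedules over a small random cost table, and
#' death flags are random. The enumeration oracle gives its closed-form
#' expected cost.
#'
#' @param seed Integer seed.
#' @param depth Maximum tree depth (>= 1).
#' @param n_procedures Number of procedures in the random cost table.
#' @return A list with `tree` (a [decision_tree()]) and `cost_table`
#'   (a [cost_table()]; pre and post epochs share TPP/OOP prices).
#' @export
generate_random_model <- function(seed = 1, depth = 3, n_procedures = 4) {
  stopifnot(depth >= 1)
  set.seed(seed)
  ids <- paste0("proc", seq_len(n_procedures))
  tpp <- round(stats::runif(n_procedures, 10, 5000), 1)
  oop <- round(stats::runif(n_procedures, 1, 2000), 1)
  bdl <- round(stats::runif(n_procedures, 0, 3000), 1)
  ct <- cost_table(ids, ids, pre_tpp = tpp, pre_oop = oop,
                   post_tpp = tpp, post_oop = oop, post_bdl = bdl)
  cm <- epoch_costs(ct, "post")
  counter <- 0L
  new_id <- function(prefix) {
    counter <<- counter + 1L
    paste0(prefix, counter)
  }
  stick_break <- function(k) {
    w <- stats::rexp(k)
    w / sum(w)
  }
  grow <- function(level) {
    if (level >= depth || stats::runif(1) < 0.3) {
      schedule <- matrix(stats::rpois(n_procedures * 5, 1.2) * 0.5,
                         n_procedures, 5, dimnames = list(ids, NULL))
      return(terminal_node(new_id("leaf"),
                           per_year_costs = fold_schedule(schedule, cm),
                           is_death = stats::runif(1) < 0.3,
                           schedule = schedule))
    }
    k <- sample(2:3, 1)
    chance_node(new_id("node"),
                children = lapply(seq_len(k), function(i) grow(level + 1)),
                probs = stick_break(k))
  }
  root <- chance_node(new_id("node"),
                      children = list(grow(1), grow(1)),
                      probs = stick_break(2))
  list(tree = decision_tree(root, name = paste0("random_", seed)),
       cost_table = ct)
}
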