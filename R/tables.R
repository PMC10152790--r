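#' Procedure cost table for the Lebanon bladder-cancer model
#'
#' All 18 medical procedures in the model with their per-payer costs in
#' thousand LBP, for the pre-collapse (2019) and post-collapse (2022) price
#' epochs. TPP amounts come from third-party-payer coverage databases, OOP
#' amounts are the household share, and BDL amounts are the post-collapse
#' central-bank drug subsidies (about 93% of listed drug prices at modelling
#' time; no subsidies existed pre-collapse).
#'
#' @return A [cost_table()] with 18 rows.
#' @export
bc_cost_table <- function() {
  cost_table(
    procedure_id = c(
      "consult", "urinalysis", "urine_culture", "pelvic_us", "ct_urogram",
      "tap_scan", "mmc", "bcg", "tmt", "palliative_rt", "cystoscopy",
      "turbt", "cystectomy", "ddmvac", "gem_cis", "gem_carbo",
      "immuno_1l", "immuno_2l"
    ),
    label = c(
      "Physician consultation", "Urinalysis", "Urine culture",
      "Pelvic ultrasound", "CT urogram", "TAP scan with contrast",
      "MMC instillation", "BCG instillation", "Radio-Chemo TMT",
      "Palliative radiotherapy", "Cystoscopy", "TURBT",
      "Radical cystectomy", "ddMVAC 4 cycles", "Gem-Cisplatin 4 cycles",
      "Gem-Carboplatin 4 cycles", "Immunotherapy 1st line",
      "Immunotherapy 2nd line"
    ),
    pre_tpp = c(80, 5.6, 24, 118, 224, 224, 444, 314, 6373, 2000, 798,
                1796, 8579, 7028, 5856, 5279, 30548, 100884),
    pre_oop = c(20, 1.4, 6, 29, 56, 56, 111, 79, 12200, 3000, 63,
                135, 697, 563, 427, 356, 0, 0),
    post_tpp = c(80, 5.6, 24, 118, 224, 224, 444, 314, 6373, 2000, 1883,
                 4673, 19667, 7028, 5856, 5279, 30548, 100884),
    post_oop = c(320, 46, 196, 582, 1176, 3116, 467, 471, 89133, 32000,
                 4762, 10290, 52017, 6189, 6121, 6318, 0, 0),
    post_bdl = c(0, 0, 0, 0, 0, 0, 5250, 2800, 9660, 0, 0,
                 0, 0, 64512, 47600, 38472, 74455, 1244547)
  )
}

#' Expert-elicited pathway probabilities (percent)
#'
#' The Delphi-consensus probability parameters of the model, as percentages,
#' for the pre- and post-collapse scenarios: the diagnosis gate (timely
#' TURBT vs doing nothing, and among the latter, late TURBT vs never
#' returning), the optimal / sub-optimal / no-follow-up split per stage, the
#' neoadjuvant-chemotherapy-plus-cystectomy vs tri-modal-therapy split within
#' optimal muscle-invasive care, and the first-line chemotherapy vs
#' immunotherapy split for treated metastatic disease.
#'
#' @return A data frame with columns `group`, `item`, `pre`, `post`
#'   (percent, integers).
#' @export
bc_probability_table <- function() {
  tab <- rbind(
    c("diagnosis",    "turbt",       95, 90),
    c("diagnosis",    "nothing",      5, 10),
    c("diagnosis",    "late_turbt",  65, 60),
    c("diagnosis",    "never_back",  35, 40),
    c("low",          "optimal",     50, 30),
    c("low",          "suboptimal",  30, 40),
    c("low",          "none",        20, 30),
    c("intermediate", "optimal",     40, 30),
    c("intermediate", "suboptimal",  50, 50),
    c("intermediate", "none",        10, 20),
    c("high",         "optimal",     30, 20),
    c("high",         "suboptimal",  65, 70),
    c("high",         "none",         5, 10),
    c("very_high",    "optimal",     30, 20),
    c("very_high",    "suboptimal",  65, 70),
    c("very_high",    "none",         5, 10),
    c("invasive",     "optimal",     80, 60),
    c("invasive",     "nac_rc",      80, 90),
    c("invasive",     "tmt",         20, 10),
    c("invasive",     "suboptimal",  15, 30),
    c("invasive",     "none",         5, 10),
    c("metastatic",   "treatment",   90, 80),
    c("metastatic",   "chemo_1l",    85, 85),
    c("metastatic",   "immuno_1l",   15, 15),
    c("metastatic",   "none",        10, 20)
  )
  data.frame(group = tab[, 1], item = tab[, 2],
             pre = as.numeric(tab[, 3]), post = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Pathway adherence probabilities for one scenario epoch
#'
#' Converts the percent table of [bc_probability_table()] into the exact
#' probabilities used by the model builder (percent integers divided by 100).
#'
#' @param epoch `"pre"` or `"post"`.
#' @return A list with components:
#'   `gate` (turbt, nothing, late_turbt, never_back),
#'   `stages` (data frame: stage, optimal, suboptimal, none),
#'   `invasive_split` (nac_rc, tmt within optimal invasive care),
#'   `metastatic` (treatment, none, chemo_1l, immuno_1l).
#' @export
bc_adherence <- function(epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  tab <- bc_probability_table()
  g <- function(group, item) tab[[epoch]][tab$group == group &
                                            tab$item == item] / 100
  stages <- c("low", "intermediate", "high", "very_high", "invasive")
  list(
    gate = c(turbt = g("diagnosis", "turbt"),
             nothing = g("diagnosis", "nothing"),
             late_turbt = g("diagnosis", "late_turbt"),
             never_back = g("diagnosis", "never_back")),
    stages = data.frame(
      stage = c(stages, "metastatic"),
      optimal = c(vapply(stages, g, numeric(1), item = "optimal"),
                  g("metastatic", "treatment")),
      suboptimal = c(vapply(stages, g, numeric(1), item = "suboptimal"), 0),
      none = c(vapply(stages, g, numeric(1), item = "none"),
               g("metastatic", "none")),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    invasive_split = c(nac_rc = g("invasive", "nac_rc"),
                       tmt = g("invasive", "tmt")),
    metastatic_split = c(chemo_1l = g("metastatic", "chemo_1l"),
                         immuno_1l = g("metastatic", "immuno_1l"))
  )
}

#' Published headline cost results (reported means)
#'
#' The reported mean annual national costs (thousand LBP) per payer for the
#' realistic pre- and post-collapse scenarios, the zero-subsidy
#' counterfactual and the pre-collapse full-adherence counterfactual. These
#' are inputs for the closed-form comparison arithmetic (USD conversions,
#' percent changes, payer shares); they are not recomputed by the packaged
#' fixture, which approximates the original full pathway tree.
#'
#' @return A data frame with columns `scenario`, `payer`, `mean_thousand_lbp`.
#' @export
bc_reported_costs <- function() {
  data.frame(
    scenario = c(rep("pre_collapse", 3),
                 rep("post_collapse", 4),
                 rep("post_collapse_zero_subsidy", 4),
                 rep("full_adherence_pre", 3)),
    payer = c("tpp", "oop", "total",
              "tpp", "oop", "bdl", "total",
              "tpp", "oop", "bdl", "total",
              "tpp", "oop", "total"),
    mean_thousand_lbp = c(
      17459219, 2217275, 19676494,
      28181835, 63088851, 79456501, 170727187,
      28181835, 142980798, 0, 171162633,
      17395503, 2380036, 19775539
    ),
    stringsAsFactors = FALSE
  )
}

#' Scenario exchange rates and national constants
#'
#' @return A list: `incidence` (new cases per year), `rate_pre` and
#'   `rate_post` (LBP per USD), `health_expenditure_2017` (total national
#'   health expenditure, thousand LBP).
#' @export
bc_constants <- function() {
  list(incidence = 781, rate_pre = 1500, rate_post = 23000,
       health_expenditure_2017 = 6238412511)
}
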