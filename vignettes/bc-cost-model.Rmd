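---
title: "Methods: a payer-stratified decision-tree cost model for bladder cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a payer-stratified decision-tree cost model for bladder cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccost)
```

## 1. Scientific problem

Economic collapse can re-price a health system overnight: currency
devaluation multiplies the local-currency cost of imported drugs and
consumables, third-party-payer tariffs lag behind, and the difference is
absorbed by households (out-of-pocket, OOP) and by emergency central-bank
drug subsidies (BDL). `bccost` quantifies that shift for incident bladder
cancer in Lebanon: it estimates the annual national cost of managing one
year's cohort of newly diagnosed patients over a 5-year horizon,
decomposed across the three payers, **before** and **after** the 2019
collapse, and under two counterfactuals (no drug subsidy; full guideline
adherence).

The modelling approach is an incidence-based cost-of-illness analysis on a
one-shot decision tree:

* Each newly diagnosed patient enters the tree once and follows exactly
  one root-to-leaf pathway.
* Each terminal pathway $j$ carries a 5-year schedule of procedures; its
  cost is the undiscounted sum over years 1–5 and payers
  $C_j = \sum_{t=1}^{5} (c^{TPP}_{jt} + c^{OOP}_{jt} + c^{BDL}_{jt})$.
* The expected per-patient cost is $E[C] = \sum_j p_j\, C_j$ where $p_j$
  is the product of branch probabilities along pathway $j$.
* The annual national cost is $781 \times E[C]$ (781 = annual incident
  cases). All internal amounts are in **thousand Lebanese pounds (LBP)**;
  conversion to USD happens only at reporting time, at 1,500 LBP/USD
  (pre-collapse) or 23,000 LBP/USD (post-collapse).

No discounting is applied: the comparison of interest is between price
epochs at a fixed horizon, not between time profiles.

## 2. Model structure

The packaged Lebanon model (`build_bc_fixture()`) has this shape:

```
diagnosis gate ──┬─ TURBT (timely resection) ──── stage node (6 stages)
                 └─ nothing ──┬─ late TURBT ───── stage node (late mix)
                              └─ never returns ── untreated pathway
```

* **Diagnosis gate.** After the first consultation a fraction of patients
  undergoes timely transurethral resection (TURBT); of the remainder, some
  return late and some never return. Pre-collapse the gate probabilities
  are 95% / 5%, with 65% of the 5% returning late; post-collapse 90% /
  10% with 60% returning late. The products — 1.75% never diagnosed /
  3.25% diagnosed late pre-collapse, 4% / 6% post-collapse — are exposed
  by `diagnosis_gate_stats()`.
* **Stage node.** Diagnosed patients are distributed over six strata:
  four non-muscle-invasive risk groups (low, intermediate, high,
  very-high), muscle-invasive, and metastatic disease.
* **Adherence node per stage.** Each stage splits into optimal /
  suboptimal / no follow-up arms (metastatic: treatment / no treatment),
  with elicited probabilities that differ by epoch (`bc_adherence()`,
  `bc_probability_table()`). Muscle-invasive optimal care further splits
  into neoadjuvant chemotherapy + radical cystectomy versus trimodal
  therapy; metastatic treatment splits into first-line chemotherapy
  versus first-line immunotherapy.
* **Survival leaf.** Every arm ends in an alive/dead split over the
  5-year horizon. Both leaves of that split share the arm's cost
  schedule (costs are incurred along the pathway regardless of vital
  outcome), and the split is tagged `dist = "fixed"` so survival is never
  redrawn in sensitivity analysis — uncertainty propagation targets care
  probabilities and prices, not epidemiology.

This yields 78 terminal pathways per epoch.

### Inputs that are verbatim published estimates

* The **unit-cost table** (`bc_cost_table()`): 18 procedures/treatments
  with TPP, OOP and (post-collapse) BDL components in thousand LBP per
  administration, both epochs.
* The **elicited probabilities** (`bc_probability_table()`): the
  diagnosis gate, per-stage adherence splits, the invasive and metastatic
  treatment splits.
* The **headline results table** (`bc_reported_costs()`): published mean
  payer costs for the four scenarios, used by the closed-form reporting
  arithmetic (USD totals, percent changes, payer shares, share of 2017
  national health expenditure).
* Constants (`bc_constants()`): incidence 781/year, exchange rates,
  2017 national health expenditure.

### Inputs that are package design choices

The source analysis does not publish its per-arm procedure schedules,
stage mix, or arm-level survival. The fixture therefore fills these in
with guideline-flavoured approximations, **calibrated once and frozen**:

* **Stage mix** (timely vs late presentation): timely
  (25, 25, 15, 10, 20, 5)% over (low, intermediate, high, very-high,
  invasive, metastatic); late presentation shifts mass toward advanced
  disease (8, 17, 15, 15, 30, 15)%.
* **Procedure schedules**: a common diagnostic work-up (consultations,
  urinalysis, culture, ultrasound, CT urogram, cystoscopy, TURBT)
  plus per-arm surveillance cystoscopies, intravesical courses (MMC/BCG),
  surgery, chemotherapy cycles, immunotherapy and palliative care,
  spread over years 1–5 following standard urology-guideline cadence.
  Suboptimal arms thin the surveillance and treatment intensity; no-care
  arms carry only the work-up (or nothing, for never-returners).
* **5-year death probabilities per arm**: chosen so the tree's overall
  cohort mortality lands near the published figures — the calibrated
  model gives 16.0% pre-collapse (published 15.9%) and 18.1%
  post-collapse (published 17.5%). These values were fixed by hand
  against that criterion and are not re-fitted at run time.

Because of these approximations, the fixture's *expected cost* is an
emulation of the published model, not a reproduction; what the package
reproduces exactly is the published cost table, probability table, and
all reporting arithmetic over the published scenario means.

## 3. Probabilistic sensitivity analysis

`run_psa()` propagates parameter uncertainty by Monte Carlo (default
100,000 runs; the examples and tests use 2,000–20,000):

* **Costs.** Each non-zero payer component of each procedure is redrawn
  from a Gamma distribution with mean equal to the point estimate and SD
  equal to 20% of the mean (shape 25, scale mean/25). Drawing per
  *payer component* rather than per procedure keeps the payer
  decomposition coherent under uncertainty. Terminal costs are then
  recomputed from the redrawn cost matrix through the stored procedure
  schedules.
* **Two-branch probabilities** are redrawn from a Beta-PERT distribution
  with mode at the point estimate, min/max at mode ± 20% (clamped to
  [0, 1]) and shape parameter 4 — the conventional PERT smoothing.
  Note that when clamping is asymmetric (e.g. mode 0.95 gives bounds
  (0.76, 1.0)), the PERT mean is not the mode, so the PSA mean
  legitimately differs from the deterministic expectation.
* **Multi-branch probabilities** ($k \ge 3$) are redrawn jointly from a
  Dirichlet with $\alpha_i = 100 \times p_i$, i.e. concentrations on the
  *percent* scale. This keeps branch draws on the simplex by
  construction and gives component SDs comparable to the two-branch PERT
  spread.
* **Frozen nodes.** Branches with degenerate probabilities (0/1) and
  nodes tagged `dist = "fixed"` (the survival leaves) are never redrawn.
  `prob_uncertainty = FALSE` freezes everything, which is useful for
  verifying that the PSA machinery reproduces the deterministic
  expectation exactly.

Uncertainty is summarised as the percentile 95% interval of the draws
(2.5th/97.5th percentiles) plus the min–max envelope; both are reported
because the source analysis quotes ranges. Percentile intervals are the
primary interval.

### Reproducibility

Each parameter draws from its own RNG sub-stream, seeded by
`bitwXor(root_seed mod 2147483629, hash(parameter_id))` with a 31-bit
string hash. Consequences:

* a given `psa_config(seed = s)` reproduces the full draw matrix bitwise;
* the *same parameter* gets the *same draws* across scenarios that share
  it — e.g. the zero-subsidy counterfactual's TPP draws are identical to
  the realistic post-collapse scenario's, so their difference isolates
  the subsidy-reassignment effect rather than Monte Carlo noise.

## 4. Scenarios and counterfactuals

`scenario_config()` defines four labels:

| label | epoch | transform |
|---|---|---|
| `pre_collapse` | pre | none |
| `post_collapse` | post | none |
| `post_collapse_zero_subsidy` | post | `apply_zero_subsidy()`: every BDL amount is reassigned to OOP (item totals conserved, TPP untouched) |
| `full_adherence_pre` | pre | `apply_full_adherence()`: diagnosis gate and all optimal-care probabilities set to 1 |

`run_scenario()` builds the tree, runs the PSA, and returns the payer
summary (LBP and USD), the deterministic expectation, and cohort
mortality; `compare_scenarios()` reports differences and percent changes.

## 5. Worked example

```{r, eval = FALSE}
library(bccost)

cfg <- psa_config(n_runs = 20000, seed = 1)
pre  <- run_scenario("pre_collapse",  cfg)
post <- run_scenario("post_collapse", cfg)

post$summary                 # payer means, 95% CI, min-max, shares, USD
compare_scenarios(pre, post) # differences and percent changes

# closed-form reporting arithmetic over the published means
rep <- bc_reported_costs()
k   <- bc_constants()
tot <- function(s) rep$mean_thousand_lbp[rep$scenario == s &
                                         rep$payer == "total"]
convert_to_usd(tot("pre_collapse"),  k$rate_pre)   # 13,117,662 USD
convert_to_usd(tot("post_collapse"), k$rate_post)  #  7,422,921 USD
round_half_away(percent_change(tot("pre_collapse"),
                               tot("post_collapse")))  # +768% in LBP
```

## 6. Model I/O and the random generator

* `write_model_config()` / `read_model_config()` round-trip a complete
  model (tree, cost table, scenario) through YAML; the layout is
  documented in `inst/extdata/model-config-schema.md`. Loading always
  re-validates (unique node ids, probabilities summing to one, 5-year
  cost schedules).
* `write_report()` emits a TSV per-scenario payer report;
  `write_manifest()` records seed, run count, package version and output
  files. `run_analysis_suite()` drives the whole four-scenario analysis.
* `generate_random_model(seed, depth)` produces random valid trees
  (stick-breaking branch probabilities, random schedules priced against
  the packaged cost table, random death flags) for property-based
  testing: the recursive evaluator is checked against an independent
  path-enumeration oracle on 100 such trees.

## 7. Limitations

* Stage mix, schedules and arm survival are calibrated approximations
  (section 2); per-stage cost breakdowns from the fixture are indicative
  only.
* The 20% SD for cost Gammas and the ±20% PERT range are global
  conventions, not parameter-specific elicitations.
* One-shot tree, no discounting, fixed incidence: the model prices one
  incident cohort under fixed epoch prices and does not project dynamics.
* Exchange-rate pass-through is embedded in the published post-collapse
  price list; the package does not model the rate itself as uncertain.
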