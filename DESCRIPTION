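Package: bccost
Title: Decision-Tree Cost-of-Illness Modelling of Bladder Cancer Across Payers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An incidence-based, payer-stratified cost-of-illness engine for
    bladder cancer built around a one-shot decision tree over a 5-year
    follow-up horizon. Costs are decomposed across third-party payers,
    out-of-pocket household payments and central-bank drug subsidies, and
    parameter uncertainty is propagated by multi-way probabilistic
    sensitivity analysis (Gamma costs, Beta-PERT and Dirichlet branch
    probabilities, Monte Carlo simulation with percentile confidence
    intervals). Ships a fully specified Lebanon bladder-cancer model
    instance covering pre- and post-economic-collapse price epochs, a
    zero-subsidy counterfactual and a full-adherence counterfactual, plus
    a random-model generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
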