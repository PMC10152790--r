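test_that("degenerate PSA collapses to the deterministic expectation", {
  m <- generate_random_model(21, depth = 3)
  res <- run_psa(m$tree, cost_matrix = NULL, incidence = 781,
                 config = psa_config(n_runs = 50, seed = 1),
                 prob_uncertainty = FALSE)
  det <- annual_national_cost(781, expected_cost(m$tree))
  expect_equal(unname(res$mean[c("tpp", "oop", "bdl")]), unname(unclass(det)),
               tolerance = 1e-12)
  # every run identical, CI width zero
  expect_equal(max(res$draws[, "total"]) - min(res$draws[, "total"]), 0)
  expect_equal(unname(res$ci["upper", ]) - unname(res$ci["lower", ]),
               rep(0, 4))
})

test_that("PSA mean tracks the closed-form expectation of a single gamma cost", {
  # one pathway, fixed probability 1, one procedure with gamma cost:
  # by linearity the PSA mean must equal the procedure's mean cost
  ct <- cost_table("p1", "P1", pre_tpp = 200, pre_oop = 50,
                   post_tpp = 200, post_oop = 50, post_bdl = 0)
  cm <- epoch_costs(ct, "pre")
  schedule <- matrix(c(1, 0, 0, 0, 0), 1, 5, dimnames = list("p1", NULL))
  leaf <- terminal_node("only", per_year_costs = t(schedule) %*% cm,
                        schedule = schedule)
  tree <- decision_tree(chance_node("root", list(leaf, flat_terminal("nil")),
                                    c(1, 0), dist = "fixed"))
  res <- run_psa(tree, cost_matrix = cm, incidence = 1,
                 config = psa_config(n_runs = 20000, seed = 5))
  se_tpp <- sd(res$draws[, "tpp"]) / sqrt(nrow(res$draws))
  expect_lt(abs(res$mean[["tpp"]] - 200), 3 * se_tpp)
  se_oop <- sd(res$draws[, "oop"]) / sqrt(nrow(res$draws))
  expect_lt(abs(res$mean[["oop"]] - 50), 3 * se_oop)
})

test_that("same seed reproduces a PSA bitwise; runs respect the accounting identity", {
  m <- generate_random_model(22, depth = 4)
  cm <- epoch_costs(m$cost_table, "post")
  cfg <- psa_config(n_runs = 2000, seed = 99)
  r1 <- run_psa(m$tree, cm, incidence = 781, config = cfg)
  r2 <- run_psa(m$tree, cm, incidence = 781, config = cfg)
  expect_identical(r1$draws, r2$draws)
  expect_equal(r1$draws[, "total"],
               rowSums(r1$draws[, c("tpp", "oop", "bdl")]))
})

test_that("Monte Carlo error shrinks toward the unclamped expectation as runs grow", {
  # all PERT modes <= 5/6 keep bounds symmetric inside [0,1], so the
  # PSA mean converges to the deterministic expected cost
  t1 <- flat_terminal("a", tpp = 1000)
  t2 <- flat_terminal("b", tpp = 200)
  tree <- two_leaf_tree(0.6, t1, t2)
  det <- expected_cost(tree)[["tpp"]]
  err <- vapply(c(2000, 20000, 100000), function(n) {
    r <- run_psa(tree, config = psa_config(n_runs = n, seed = 31))
    abs(r$mean[["tpp"]] - det)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3] / det, 0.005)
})

test_that("percentile intervals cover the expectation on a well-behaved fixture", {
  t1 <- flat_terminal("a", oop = 500)
  t2 <- flat_terminal("b", oop = 100)
  tree <- two_leaf_tree(0.5, t1, t2)
  det <- expected_cost(tree)[["oop"]]
  hits <- vapply(1:100, function(s) {
    r <- run_psa(tree, config = psa_config(n_runs = 400, seed = s))
    r$ci["lower", "oop"] <= det && det <= r$ci["upper", "oop"]
  }, logical(1))
  expect_gte(mean(hits), 0.94)
})

test_that("summaries report shares that recompose the total", {
  m <- generate_random_model(23, depth = 3)
  res <- run_psa(m$tree, epoch_costs(m$cost_table, "post"),
                 incidence = 781, config = psa_config(n_runs = 2000, seed = 3))
  s <- psa_summary(res)
  payer_rows <- s$payer != "TOTAL"
  expect_equal(sum(s$share_raw[payer_rows]), 100, tolerance = 1e-9)
  expect_lte(abs(sum(s$share_pct[payer_rows]) - 100), 1) # rounding slack
  expect_equal(s$mean[s$payer == "TOTAL"], sum(s$mean[payer_rows]))
})

test_that("PSA rejects impossible requests", {
  m <- generate_random_model(24, depth = 2)
  expect_error(run_psa(m$tree, config = psa_config(n_runs = 1)),
               "at least 2 runs")
  zero <- two_leaf_tree(0.5, flat_terminal("a"), flat_terminal("b"))
  rz <- run_psa(zero, config = psa_config(n_runs = 10, seed = 1))
  expect_error(psa_summary(rz), "zero")
})
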