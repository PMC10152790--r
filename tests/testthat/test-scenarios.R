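test_that("display rounding is half away from zero", {
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.4), 2)
  expect_equal(round_half_away(767.67), 768)
  expect_equal(round_half_away(0.315, 2), 0.32)
})

test_that("LBP to USD conversion truncates for display and inverts within 1 LBP", {
  expect_equal(convert_to_usd(19676494, 1500), 13117662)
  expect_equal(convert_to_usd(170727187, 23000), 7422921)
  expect_equal(convert_to_usd(0, 1500), 0)
  expect_error(convert_to_usd(100, 0), "positive")

  # inverse conversion recovers the amount within the truncation bound
  amt <- 19676494
  usd <- convert_to_usd(amt, 1500)
  back <- usd * 1500 / 1000
  expect_lte(abs(back - amt), 1500 / 1000) # 1 LBP per truncated USD cent scale
  expect_equal(convert_to_usd(amt, 1500, display = FALSE) * 1500 / 1000, amt)
})

test_that("percent changes reproduce the headline comparisons after rounding", {
  expect_equal(round_half_away(percent_change(19676494, 170727187)), 768)
  expect_equal(round_half_away(percent_change(2217275, 63088851)), 2745)
  expect_equal(round_half_away(percent_change(17459219, 28181835)), 61)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 10), "positive baseline")
})

test_that("zero-subsidy transform reassigns BDL to OOP conserving totals", {
  ct <- bc_cost_table()
  zs <- apply_zero_subsidy(ct, "post")
  i <- which(ct$procedure_id == "ddmvac")
  expect_equal(c(zs$post_tpp[i], zs$post_oop[i], zs$post_bdl[i]),
               c(7028, 70701, 0))
  expect_equal(zs$post_tpp, ct$post_tpp)
  expect_true(all(zs$post_bdl == 0))
  expect_equal(zs$post_tpp + zs$post_oop + zs$post_bdl,
               ct$post_tpp + ct$post_oop + ct$post_bdl)
  # idempotent once BDL is zero
  expect_equal(apply_zero_subsidy(zs, "post"), zs)
  expect_error(apply_zero_subsidy(ct, "pre"), "pre-collapse")
})

test_that("full-adherence transform forces optimal care and is idempotent", {
  adh <- bc_adherence("pre")
  fa <- apply_full_adherence(adh)
  expect_true(all(fa$stages$optimal == 1))
  expect_true(all(fa$stages$suboptimal == 0))
  expect_true(all(fa$stages$none == 0))
  expect_equal(unname(fa$gate[c("turbt", "nothing")]), c(1, 0))
  expect_equal(apply_full_adherence(fa), fa)
  sums <- fa$stages$optimal + fa$stages$suboptimal + fa$stages$none
  expect_equal(sums, rep(1, nrow(fa$stages)))
})

test_that("health-expenditure share reproduces the 0.32% figure", {
  expect_equal(share_of_health_expenditure(19676494, 6238412511), 0.32)
  expect_equal(share_of_health_expenditure(0, 100), 0)
  expect_equal(share_of_health_expenditure(7, 7), 100)
  expect_error(share_of_health_expenditure(1, 0), "positive")
})

test_that("diagnosis-gate statistics multiply the gate probabilities", {
  pre <- diagnosis_gate_stats(bc_adherence("pre"))
  post <- diagnosis_gate_stats(bc_adherence("post"))
  expect_equal(pre[["never_return"]], 0.05 * 0.35)
  expect_equal(pre[["never_return"]], 0.0175)
  expect_equal(post[["never_return"]], 0.04)
  expect_equal(pre[["late_care"]], 0.0325)
  expect_equal(post[["late_care"]], 0.06)

  adh <- bc_adherence("pre")
  adh$gate[["nothing"]] <- 0
  expect_equal(unname(diagnosis_gate_stats(adh)), c(0, 0))
})

test_that("stage cost breakdown recomputes shares from raw costs", {
  df <- data.frame(stage = "only", total = 42)
  expect_equal(stage_cost_breakdown(df)$share_raw, 100)

  df5 <- data.frame(stage = letters[1:5], total = rep(3, 5))
  expect_equal(stage_cost_breakdown(df5)$share_pct, rep(20, 5))

  set.seed(10)
  dfr <- data.frame(stage = letters[1:6], total = runif(6, 1, 100))
  bd <- stage_cost_breakdown(dfr)
  expect_equal(bd$share_raw, 100 * dfr$total / sum(dfr$total))
  expect_equal(sum(bd$share_raw), 100, tolerance = 1e-12)
  expect_error(stage_cost_breakdown(data.frame(stage = "a", total = 0)),
               "zero")
})

test_that("scenario configs carry the study conditions", {
  pre <- scenario_config("pre_collapse")
  expect_equal(pre$exchange_rate, 1500)
  expect_equal(pre$incidence, 781)
  post <- scenario_config("post_collapse")
  expect_equal(post$exchange_rate, 23000)
  zs <- scenario_config("post_collapse_zero_subsidy")
  expect_true(zs$zero_subsidy)
  fa <- scenario_config("full_adherence_pre")
  expect_true(all(fa$adherence$stages$optimal == 1))
  expect_error(scenario_config("custom_thing"), "explicit epoch")
})
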