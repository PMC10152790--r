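test_that("packaged cost table reproduces every cell of the price list", {
  ct <- bc_cost_table()
  expect_equal(nrow(ct), 18)
  # column checksums entered independently from the printed table
  expect_equal(sum(ct$pre_tpp), 170574.6)
  expect_equal(sum(ct$pre_oop), 17799.4)
  expect_equal(sum(ct$pre_bdl), 0)
  expect_equal(sum(ct$post_tpp), 185624.6)
  expect_equal(sum(ct$post_oop), 213204)
  expect_equal(sum(ct$post_bdl), 1487296)
  # spot cells
  row <- function(id) ct[ct$procedure_id == id, ]
  expect_equal(unlist(row("consult")[c("pre_tpp", "pre_oop", "post_tpp",
                                       "post_oop", "post_bdl")],
                      use.names = FALSE),
               c(80, 20, 80, 320, 0))
  expect_equal(row("urinalysis")$pre_oop, 1.4)
  expect_equal(row("tmt")$post_oop, 89133)
  expect_equal(row("immuno_2l")$post_bdl, 1244547)
  expect_equal(row("cystoscopy")$post_tpp, 1883)
})

test_that("packaged probability table reproduces the elicited values", {
  tab <- bc_probability_table()
  expect_equal(nrow(tab), 25)
  cell <- function(g, i, e) tab[[e]][tab$group == g & tab$item == i]
  expect_equal(cell("diagnosis", "turbt", "pre"), 95)
  expect_equal(cell("diagnosis", "turbt", "post"), 90)
  expect_equal(cell("diagnosis", "never_back", "pre"), 35)
  expect_equal(cell("low", "optimal", "pre"), 50)
  expect_equal(cell("low", "none", "post"), 30)
  expect_equal(cell("intermediate", "suboptimal", "pre"), 50)
  expect_equal(cell("high", "suboptimal", "post"), 70)
  expect_equal(cell("very_high", "optimal", "pre"), 30)
  expect_equal(cell("invasive", "nac_rc", "post"), 90)
  expect_equal(cell("metastatic", "chemo_1l", "pre"), 85)
  # every adherence triple is a valid probability vector after /100
  for (e in c("pre", "post")) {
    adh <- bc_adherence(e)
    sums <- adh$stages$optimal + adh$stages$suboptimal + adh$stages$none
    expect_equal(sums, rep(1, 6))
    expect_equal(unname(adh$gate[["turbt"]] + adh$gate[["nothing"]]), 1)
    expect_equal(unname(adh$gate[["late_turbt"]] + adh$gate[["never_back"]]),
                 1)
  }
})

test_that("fixture trees are valid and pre-collapse carries no subsidies", {
  for (epoch in c("pre", "post")) {
    tree <- build_bc_fixture(epoch)
    paths <- enumerate_paths(tree)
    expect_equal(sum(vapply(paths, `[[`, numeric(1), "prob")), 1,
                 tolerance = 1e-9)
  }
  expect_equal(expected_cost(build_bc_fixture("pre"))[["bdl"]], 0)
  expect_gt(expected_cost(build_bc_fixture("post"))[["bdl"]], 0)
})

test_that("fixture gate examples match the elicited splits", {
  pre <- build_bc_fixture("pre")
  p <- unlist(pre$root$probs)
  expect_equal(p, c(0.95, 0.05))
  post <- build_bc_fixture("post")
  met <- bc_adherence("post")$stages
  expect_equal(met$none[met$stage == "metastatic"], 0.20)
})

test_that("fixture mortality sits near the reported rates and rises post-collapse", {
  m_pre <- mortality_rate(build_bc_fixture("pre"))
  m_post <- mortality_rate(build_bc_fixture("post"))
  expect_gt(m_post, m_pre)
  expect_lt(abs(m_pre - 0.159), 0.02)
  expect_lt(abs(m_post - 0.175), 0.02)
})

test_that("post-collapse care costs more than pre-collapse in LBP", {
  pre <- total_cost(expected_cost(build_bc_fixture("pre")))
  post <- total_cost(expected_cost(build_bc_fixture("post")))
  expect_gt(post / pre, 4) # the currency collapse dominates
})

test_that("worse adherence never lowers mortality or raises optimal-care mass", {
  adh <- bc_adherence("pre")
  base <- mortality_rate(build_bc_fixture("pre", adherence = adh))
  worse <- perturb_adherence(adh, "worse", amount = 0.05)
  m_worse <- mortality_rate(build_bc_fixture("pre", adherence = worse))
  expect_gte(m_worse, base)
  # shifting everything to no-follow-up is the worst case
  all_none <- adh
  all_none$stages$none <- all_none$stages$none + all_none$stages$optimal +
    all_none$stages$suboptimal
  all_none$stages$optimal <- 0
  all_none$stages$suboptimal <- 0
  m_none <- mortality_rate(build_bc_fixture("pre", adherence = all_none))
  expect_gte(m_none, m_worse)

  # zero shift leaves the fixture unchanged; rows stay probability vectors
  expect_equal(perturb_adherence(adh, "worse", amount = 0), adh)
  sums <- worse$stages$optimal + worse$stages$suboptimal + worse$stages$none
  expect_equal(sums, rep(1, 6))
  expect_error(perturb_adherence(adh, "worse", amount = 0.99), "negative")
})

test_that("random models are reproducible and depth-1 is oracle-checkable", {
  a <- generate_random_model(77, depth = 3)
  b <- generate_random_model(77, depth = 3)
  expect_identical(a, b)
  d1 <- generate_random_model(5, depth = 1)$tree
  expect_equal(unclass(expected_cost(d1)), oracle_expected_cost(d1))
})
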