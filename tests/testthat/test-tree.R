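test_that("path enumeration multiplies probabilities along each pathway", {
  # identity case: one effective pathway
  t1 <- flat_terminal("only", tpp = 100)
  tree <- two_leaf_tree(1, t1, flat_terminal("nil"))
  paths <- enumerate_paths(tree)
  expect_equal(vapply(paths, `[[`, numeric(1), "prob"), c(1, 0))

  # diagnosis gate product: do-nothing 5% then never-return 35%
  never <- flat_terminal("never", oop = 10)
  late <- flat_terminal("late", oop = 5)
  care <- flat_terminal("care", tpp = 50)
  nothing <- chance_node("nothing", list(late, never), c(0.65, 0.35))
  gate <- decision_tree(chance_node("gate", list(care, nothing),
                                    c(0.95, 0.05)))
  p <- enumerate_paths(gate)
  ids <- vapply(p, function(x) x$terminal$pathway_id, character(1))
  expect_equal(p[[which(ids == "never")]]$prob, 0.05 * 0.35)
  expect_equal(p[[which(ids == "never")]]$prob, 0.0175)

  # random binary trees: path probabilities equal hand products, sum to 1
  set.seed(42)
  for (i in 1:10) {
    probs <- runif(3)
    mk <- function(id) flat_terminal(id, tpp = runif(1, 1, 10))
    t <- decision_tree(chance_node("a", list(
      chance_node("b", list(mk("l1"), mk("l2")), c(probs[2], 1 - probs[2])),
      chance_node("c", list(mk("l3"), mk("l4")), c(probs[3], 1 - probs[3]))
    ), c(probs[1], 1 - probs[1])))
    got <- vapply(enumerate_paths(t), `[[`, numeric(1), "prob")
    want <- c(probs[1] * probs[2], probs[1] * (1 - probs[2]),
              (1 - probs[1]) * probs[3], (1 - probs[1]) * (1 - probs[3]))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("tree validation catches structural violations", {
  t1 <- flat_terminal("x"); t2 <- flat_terminal("y")
  expect_error(chance_node("n", list(t1, t2), c(0.7, 0.4)), "sum to")
  expect_error(chance_node("n", list(t1), 1), "at least 2")
  expect_error(
    decision_tree(chance_node("n", list(flat_terminal("dup"),
                                        flat_terminal("dup")), c(0.5, 0.5))),
    "duplicate"
  )
})

test_that("unresolved distribution references are reported by node id", {
  spec <- beta_pert_spec(0.3)
  node <- chance_node("gate2", list(flat_terminal("a"), flat_terminal("b")),
                      probs = list(spec, 0.7))
  tree <- structure(list(root = node, name = "m"), class = "decision_tree")
  expect_error(enumerate_paths(tree), "unresolved parameter.*gate2")
  resolved <- resolve_tree(tree)
  expect_equal(enumerate_paths(resolved)[[1]]$prob, 0.3)
})

test_that("expected cost matches trivial cases and the enumeration oracle", {
  # single terminal, p = 1, year-1 tpp = 100
  tree <- two_leaf_tree(1, flat_terminal("a", tpp = 100), flat_terminal("b"))
  expect_equal(unclass(expected_cost(tree)),
               c(tpp = 100, oop = 0, bdl = 0))

  # symmetry: two terminals at 0.5 with oop 0 and 200
  tree <- two_leaf_tree(0.5, flat_terminal("a"), flat_terminal("b", oop = 200))
  expect_equal(expected_cost(tree)[["oop"]], 100)

  # oracle equivalence on 50 random trees
  for (seed in 1:50) {
    tree <- generate_random_model(seed, depth = sample(2:6, 1))$tree
    got <- unclass(expected_cost(tree))
    want <- oracle_expected_cost(tree)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("expected cost is monotone in terminal costs", {
  set.seed(99)
  tree <- generate_random_model(11, depth = 4)$tree
  base <- expected_cost(tree)
  bump_first_leaf <- function(node) {
    if (inherits(node, "terminal_node")) {
      node$per_year_costs[1, "oop"] <- node$per_year_costs[1, "oop"] + 500
      return(node)
    }
    node$children[[1]] <- bump_first_leaf(node$children[[1]])
    node
  }
  tree$root <- bump_first_leaf(tree$root)
  expect_gte(expected_cost(tree)[["oop"]], base[["oop"]])
  expect_equal(expected_cost(tree)[["tpp"]], base[["tpp"]])
})

test_that("annual national cost is linear and invertible", {
  v <- payer_costs(5, 2, 1)
  expect_equal(unclass(annual_national_cost(0, v)), c(tpp = 0, oop = 0, bdl = 0))
  expect_equal(annual_national_cost(10, v)[["tpp"]], 50)

  # incidence 781 cross-checked by repeated addition
  acc <- payer_costs(0, 0, 0)
  for (i in 1:781) acc <- acc + v
  expect_equal(unclass(annual_national_cost(781, v)), unclass(acc))
  expect_equal(unclass(annual_national_cost(781, v) / 781), unclass(v))
})

test_that("mortality aggregates death-flagged path probabilities", {
  all_death <- two_leaf_tree(0.3, flat_terminal("a", is_death = TRUE),
                             flat_terminal("b", is_death = TRUE))
  expect_equal(mortality_rate(all_death), 1)
  none <- two_leaf_tree(0.3, flat_terminal("a"), flat_terminal("b"))
  expect_equal(mortality_rate(none), 0)
  for (seed in 1:20) {
    tree <- generate_random_model(seed + 100, depth = 4)$tree
    expect_equal(mortality_rate(tree), oracle_mortality(tree),
                 tolerance = 1e-12)
  }
})
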