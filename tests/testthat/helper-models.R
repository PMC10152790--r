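# small model builders shared across tests

# terminal whose year-1 cost is the given payer vector, zero afterwards
flat_terminal <- function(id, tpp = 0, oop = 0, bdl = 0, is_death = FALSE,
                          stage = NULL) {
  costs <- matrix(0, 5, 3)
  costs[1, ] <- c(tpp, oop, bdl)
  terminal_node(id, per_year_costs = costs, is_death = is_death,
                stage = stage)
}

# two-leaf tree with probability p on the first terminal
two_leaf_tree <- function(p, t1, t2) {
  decision_tree(chance_node("root", children = list(t1, t2),
                            probs = c(p, 1 - p)))
}

# path-enumeration oracle for the expected cost (independent of the
# recursive evaluator)
oracle_expected_cost <- function(tree) {
  paths <- enumerate_paths(tree)
  Reduce(`+`, lapply(paths, function(p) {
    p$prob * colSums(p$terminal$per_year_costs)
  }))
}

oracle_mortality <- function(tree) {
  sum(vapply(enumerate_paths(tree), function(p) {
    p$prob * as.numeric(p$terminal$is_death)
  }, numeric(1)))
}
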