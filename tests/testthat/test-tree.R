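test_that("terminal and symmetric chance rollback reproduce hand values", {
  expect_payoff_equal(rollback(terminal_node("state", 195, 0.6)), 195, 0.6)
  tree <- chance_node("coin", c(h = 0.5, t = 0.5),
                      list(terminal_node("a", 0, 1),
                           terminal_node("b", 100, 0)))
  expect_payoff_equal(rollback(tree), 50, 0.5)
})

test_that("rollback equals the brute-force path-sum oracle on an asymmetric tree", {
  tree <- three_level_tree()
  oracle <- brute_force_expectation(tree)
  # frozen from the oracle: 0.5*(0.42*10 + 0.58*(0.2*100 + 0.8*5)) + 0.5*195
  expect_equal(unname(oracle["cost"]), 106.56, tolerance = 1e-12)
  # 0.5*(0.42*1 + 0.58*(0.2*0 + 0.8*0.9)) + 0.5*0.6
  expect_equal(unname(oracle["effect"]), 0.7188, tolerance = 1e-12)
  rb <- rollback(tree)
  expect_equal(rb$cost, unname(oracle["cost"]), tolerance = 1e-12)
  expect_equal(rb$effect, unname(oracle["effect"]), tolerance = 1e-12)
  pe <- path_expectation(tree)
  expect_equal(pe$cost, rb$cost, tolerance = 1e-12)
  expect_equal(pe$effect, rb$effect, tolerance = 1e-12)
})

test_that("rollback is linear in payoffs and invariant to branch order", {
  scale_costs <- function(node, k) {
    if (node$kind == "terminal")
      return(terminal_node(node$label, node$payoff$cost * k,
                           node$payoff$effect))
    chance_node(node$label, node$probs,
                lapply(node$children, scale_costs, k = k))
  }
  shift_effects <- function(node, c) {
    if (node$kind == "terminal")
      return(terminal_node(node$label, node$payoff$cost,
                           node$payoff$effect + c))
    chance_node(node$label, node$probs,
                lapply(node$children, shift_effects, c = c))
  }
  tree <- three_level_tree()
  base <- rollback(tree)
  expect_equal(rollback(scale_costs(tree, 3.5))$cost, 3.5 * base$cost,
               tolerance = 1e-12)
  expect_equal(rollback(shift_effects(tree, 0.25))$effect,
               base$effect + 0.25, tolerance = 1e-12)
  flipped <- chance_node("root", tree$probs[c(2, 1)],
                         tree$children[c(2, 1)])
  expect_equal(rollback(flipped)$cost, base$cost, tolerance = 1e-12)
  expect_equal(rollback(flipped)$effect, base$effect, tolerance = 1e-12)
})

test_that("validation reports sum and range violations without raising", {
  good <- three_level_tree()
  expect_identical(nrow(validate_tree(good)), 0L)

  bad_sum <- chance_node("oversum", c(a = 0.6, b = 0.6),
                         list(terminal_node("x", 0, 0),
                              terminal_node("y", 0, 0)))
  v <- validate_tree(bad_sum)
  expect_identical(v$type, "sum")
  expect_identical(v$node, "oversum")
  expect_error(rollback(bad_sum), "oversum")

  bad_range <- chance_node("negprob", c(a = -0.1, b = 1.1),
                           list(terminal_node("x", 0, 0),
                                terminal_node("y", 0, 0)))
  v2 <- validate_tree(bad_range)
  expect_true("range" %in% v2$type)
})

test_that("node constructors enforce structural invariants", {
  expect_error(payoff(-1, 0.5), ">= 0")
  expect_error(payoff(10, -0.5), ">= 0")
  expect_error(chance_node("one", c(a = 1), list(terminal_node("x", 0, 0))),
               ">= 2 branches")
  expect_error(decision_node("d", list(a = terminal_node("x", 0, 0))),
               ">= 2 alternatives")
  expect_error(rollback(decision_node("d",
    list(a = terminal_node("x", 0, 0), b = terminal_node("y", 1, 1)))),
    "evaluate_alternatives")
})

test_that("evaluate_alternatives returns one payoff per arm, without selecting", {
  root <- decision_node("root",
    list(A = terminal_node("a", 10, 1), B = terminal_node("b", 20, 2)))
  res <- evaluate_alternatives(root)
  expect_named(res, c("A", "B"))
  expect_payoff_equal(res$A, 10, 1)
  expect_payoff_equal(res$B, 20, 2)

  twin <- decision_node("root",
    list(A = three_level_tree(), B = three_level_tree()))
  tw <- evaluate_alternatives(twin)
  expect_equal(tw$A$cost, tw$B$cost, tolerance = 1e-15)
  expect_equal(tw$A$effect, tw$B$effect, tolerance = 1e-15)
})

test_that("tree serialization round-trips losslessly in JSON and YAML", {
  tree <- decision_node("root",
    list(treat_all = three_level_tree(),
         selective = terminal_node("leaf", 1 / 3, 0.1)))
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_tree(tree, f)
    back <- read_tree(f)
    expect_identical(tree_to_list(back), tree_to_list(tree))
    ev1 <- evaluate_alternatives(tree); ev2 <- evaluate_alternatives(back)
    expect_equal(ev1$treat_all$cost, ev2$treat_all$cost, tolerance = 0)
    expect_equal(ev1$selective$cost, ev2$selective$cost, tolerance = 0)
  }
})

test_that("serialized probability expressions resolve against parameters", {
  lst <- list(kind = "chance", label = "tb_status", branches = list(
    list(name = "tb", prob = "prevalence_tb",
         child = list(kind = "terminal", label = "a", cost = 1, effect = 0)),
    list(name = "no_tb", prob = "1 - prevalence_tb",
         child = list(kind = "terminal", label = "b", cost = 0, effect = 1))))
  tree <- tree_from_list(lst, params = base_params())
  expect_equal(unname(tree$probs), c(0.5, 0.5))
  expect_error(tree_from_list(list(kind = "chance", label = "x", branches = list(
    list(name = "a", prob = "system('ls')",
         child = list(kind = "terminal", label = "a", cost = 0, effect = 0)),
    list(name = "b", prob = 0.5,
         child = list(kind = "terminal", label = "b", cost = 0, effect = 0))))),
    "disallowed")
})
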