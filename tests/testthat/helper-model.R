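# Shared fixtures and the independent brute-force oracle.

base_params <- function() default_parameters()

# structure with every stochastic-utility refinement off: the simplest
# reading, convenient for hand arithmetic
st_plain <- function() structure_config(mortality_mode = "mortality_direct",
                                        soc_delayed_empiric = FALSE,
                                        sepsis_dw_applied = FALSE)

st_delayed <- function(mode = "mortality_direct")
  structure_config(mortality_mode = mode, soc_delayed_empiric = TRUE,
                   sepsis_dw_applied = FALSE)

# Independent expectation oracle: plain recursive path-probability sum,
# written before (and kept independent of) rollback()/enumerate_paths().
brute_force_expectation <- function(node, prob = 1) {
  if (node$kind == "terminal")
    return(c(cost = prob * node$payoff$cost,
             effect = prob * node$payoff$effect))
  acc <- c(cost = 0, effect = 0)
  for (i in seq_along(node$probs))
    acc <- acc + brute_force_expectation(node$children[[i]],
                                         prob * node$probs[[i]])
  acc
}

all_arm_trees <- function(params, structure) {
  out <- list()
  for (d in names(params$diagnostics)) {
    out[[paste0(d, "_treat_all")]] <- build_treat_all(params, d, structure)
    out[[paste0(d, "_selective")]] <- build_selective(params, d, structure)
  }
  out
}

# a small three-level asymmetric chance tree with known payoffs
three_level_tree <- function() {
  chance_node("root", c(a = 0.5, b = 0.5), list(
    chance_node("mid_a", c(x = 0.42, y = 0.58), list(
      terminal_node("leaf_ax", 10, 1.0),
      chance_node("deep", c(u = 0.2, v = 0.8), list(
        terminal_node("leaf_ayu", 100, 0.0),
        terminal_node("leaf_ayv", 5, 0.9))))),
    terminal_node("leaf_b", 195, 0.6)))
}

expect_payoff_equal <- function(p, cost, effect, tol = 1e-12) {
  expect_equal(p$cost, cost, tolerance = tol)
  expect_equal(p$effect, effect, tolerance = tol)
}
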