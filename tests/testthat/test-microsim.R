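test_that("a single-terminal tree simulates to its payoff with zero SE", {
  leaf <- terminal_node("alive", 42.5, 0.75)
  co <- simulate_cohort(leaf, 100, seed = 1)
  expect_true(all(co$cohort$cost == 42.5))
  expect_true(all(co$cohort$qaly == 0.75))
  expect_identical(co$summary$se_cost, 0)
  expect_identical(unname(co$summary$state_freq["alive"]), 100L)
})

test_that("fair-coin branch frequencies respect the binomial error bound", {
  tree <- chance_node("coin", c(h = 0.5, t = 0.5),
                      list(terminal_node("heads", 0, 1),
                           terminal_node("tails", 1, 0)))
  n <- 100000L
  co <- simulate_cohort(tree, n, seed = 7)
  f_heads <- co$summary$state_freq[["heads"]] / n
  expect_lt(abs(f_heads - 0.5), 4 * sqrt(0.25 / n))
})

test_that("cohort means agree with rollback within Monte-Carlo error", {
  p <- base_params(); s <- st_delayed()
  tree <- build_treat_all(p, "xpert", s)
  co <- simulate_cohort(tree, 200000L, seed = 11)
  rb <- rollback(tree)
  expect_lte(abs(co$summary$mean_cost - rb$cost),
             4 * co$summary$se_cost + 1e-9)
  expect_lte(abs(co$summary$mean_qaly - rb$effect),
             4 * co$summary$se_qaly + 1e-9)
})

test_that("per-patient records are real paths carrying that leaf's payoff", {
  p <- base_params(); s <- st_delayed("success_mediated")
  tree <- build_selective(p, "combined", s)
  co <- simulate_cohort(tree, 2000L, seed = 3)
  paths <- enumerate_paths(tree)
  key <- paste(co$cohort$path)
  expect_true(all(key %in% paths$path))
  m <- match(key, paths$path)
  expect_equal(co$cohort$cost, paths$cost[m], tolerance = 0)
  expect_equal(co$cohort$qaly, paths$effect[m], tolerance = 0)
  # terminal-state frequencies match path-probability products
  for (st in names(co$summary$state_freq)) {
    p_state <- sum(paths$prob[paths$leaf == st])
    f <- co$summary$state_freq[[st]] / co$n
    expect_lt(abs(f - p_state), 4 * sqrt(p_state * (1 - p_state) / co$n) + 1e-9)
  }
})

test_that("same seed reproduces the cohort; different seeds differ", {
  tree <- build_selective(base_params(), "lam", st_delayed())
  a <- simulate_cohort(tree, 5000L, seed = 99)
  b <- simulate_cohort(tree, 5000L, seed = 99)
  c <- simulate_cohort(tree, 5000L, seed = 100)
  expect_identical(a$cohort, b$cohort)
  expect_false(identical(a$cohort$state, c$cohort$state))
})

test_that("simulation does not disturb the caller's random stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_cohort(
    build_treat_all(base_params(), "lam", st_plain()), 100L, seed = 5))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("simulation refuses invalid trees and demands a seed", {
  bad <- chance_node("oversum", c(a = 0.6, b = 0.6),
                     list(terminal_node("x", 0, 0),
                          terminal_node("y", 0, 0)))
  expect_error(simulate_cohort(bad, 10, seed = 1), "invalid tree")
  good <- terminal_node("x", 0, 0)
  expect_error(simulate_cohort(good, 10), "seed")
})

test_that("parameter perturbation is deterministic and respects supports", {
  p <- base_params()
  a <- suppressMessages(perturb_parameters(p, "uniform_in_range", seed = 2))
  b <- suppressMessages(perturb_parameters(p, "uniform_in_range", seed = 2))
  expect_identical(a[scalar_parameter_names()], b[scalar_parameter_names()])
  draws <- vapply(1:1000, function(i)
    suppressMessages(
      perturb_parameters(p, "uniform_in_range",
                         seed = i)$p_treatment_success_sensitive),
    numeric(1))
  expect_gte(min(draws), 0.66)
  expect_lte(max(draws), 0.92)
  expect_lt(abs(mean(draws) - 0.79), 0.01)
  # zero-width ranges return the base values unchanged
  p0 <- p
  p0$ranges <- lapply(p0$ranges, function(r) rep(mean(r), 2))
  for (nm in names(p0$ranges)) p0[[nm]] <- p0$ranges[[nm]][1]
  q <- perturb_parameters(p0, "uniform_in_range", seed = 4, quiet = TRUE)
  for (nm in names(p0$ranges))
    expect_identical(q[[nm]], p0[[nm]])
})
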