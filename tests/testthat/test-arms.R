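test_that("terminal-state QALYs follow (1 - dw) * horizon", {
  p <- base_params(); s <- st_plain()
  expect_identical(qaly_for_state("dead", p, s), 0)
  expect_equal(qaly_for_state("survived_no_tb", p, s), 0.947,
               tolerance = 1e-12)
  expect_equal(qaly_for_state("survived_tb_treated", p, s), 0.9,
               tolerance = 1e-12)
  expect_equal(qaly_for_state("survived_tb_untreated", p, s), 0.601,
               tolerance = 1e-12)
  # acute sepsis decrement trims (dw_sepsis * acute) from the survivor year
  s2 <- structure_config(soc_delayed_empiric = FALSE,
                         sepsis_dw_applied = TRUE)
  a <- 7 / 365
  expect_equal(qaly_for_state("survived_no_tb", p, s2),
               0.947 * ((1 - a) + (1 - 0.31) * a), tolerance = 1e-12)
  # horizon shorter than the acute phase: decrement saturates
  p_short <- set_parameter(p, "horizon_years", 0.01)
  expect_equal(qaly_for_state("survived_no_tb", p_short, s2),
               0.947 * (1 - 0.31) * 0.01, tolerance = 1e-12)
})

test_that("treated-outcome factorization matches hand arithmetic in both modes", {
  p <- base_params()
  direct <- treated_outcome(p, st_plain())
  d_paths <- enumerate_paths(direct)
  expect_equal(sum(d_paths$prob[d_paths$leaf == "dead"]), 0.135,
               tolerance = 1e-12)

  mediated <- treated_outcome(p, st_delayed("success_mediated"))
  m_paths <- enumerate_paths(mediated)
  # 0.935 * (1 - 0.80) + 0.065 * 0.90
  expect_equal(sum(m_paths$prob[m_paths$leaf == "dead"]), 0.2455,
               tolerance = 1e-12)

  p2 <- set_parameter(set_parameter(p, "p_resistance", 0),
                      "p_treatment_success_sensitive", 1)
  m2 <- enumerate_paths(treated_outcome(p2, st_delayed("success_mediated")))
  expect_equal(sum(m2$prob[m2$leaf == "dead"]), 0, tolerance = 1e-15)
})

test_that("treat-all arm: every path carries diagnostic plus treatment cost", {
  p <- base_params(); s <- st_plain()
  tree <- build_treat_all(p, "xpert", s)
  expect_identical(nrow(validate_tree(tree)), 0L)
  paths <- enumerate_paths(tree)
  expect_true(all(abs(paths$cost - (17.42 + 195)) < 1e-12))
  # zero prevalence collapses to the suspect-without-TB outcome
  p0 <- set_parameter(p, "prevalence_tb", 0)
  rb <- rollback(build_treat_all(p0, "xpert", s))
  expect_equal(rb$effect, (1 - 0.20) * 0.947, tolerance = 1e-12)
})

test_that("selective arm: treatment cost incidence equals test positivity", {
  p <- base_params(); s <- st_plain()
  tree <- build_selective(p, "xpert", s)
  expect_identical(nrow(validate_tree(tree)), 0L)
  paths <- enumerate_paths(tree)
  treated <- abs(paths$cost - (17.42 + 195)) < 1e-12
  expect_equal(sum(paths$prob[treated]), 0.215, tolerance = 1e-12)
  expect_true(all(abs(paths$cost[!treated] - 17.42) < 1e-12))
  # with delayed empiric on, missed TB survivors also incur treatment
  s_del <- st_delayed()
  paths_d <- enumerate_paths(build_selective(p, "xpert", s_del))
  treated_d <- abs(paths_d$cost - (17.42 + 195)) < 1e-12
  expect_equal(sum(paths_d$prob[treated_d]),
               0.215 + 0.5 * (1 - 0.42) * (1 - 0.20), tolerance = 1e-12)
})

test_that("a perfect test equalizes arm effectiveness; costs differ by averted treatment", {
  p <- base_params()
  p$diagnostics$perfect <- diagnostic_profile("perfect", 1, 1, 10)
  for (s in list(st_plain(), st_delayed(), st_delayed("success_mediated"))) {
    ta <- rollback(build_treat_all(p, "perfect", s))
    soc <- rollback(build_selective(p, "perfect", s))
    expect_equal(ta$effect, soc$effect, tolerance = 1e-12)
    expect_equal(ta$cost - soc$cost, 195 * (1 - p$prevalence_tb),
                 tolerance = 1e-12)
  }
})

test_that("rollback of every arm equals the brute-force oracle", {
  p <- base_params()
  for (s in list(st_plain(), st_delayed(), st_delayed("success_mediated"),
                 structure_config())) {
    for (tree in all_arm_trees(p, s)) {
      o <- brute_force_expectation(tree)
      rb <- rollback(tree)
      expect_equal(rb$cost, unname(o["cost"]), tolerance = 1e-12)
      expect_equal(rb$effect, unname(o["effect"]), tolerance = 1e-12)
    }
  }
})

test_that("expected_outcomes matches the manually built trees", {
  p <- base_params(); s <- st_delayed()
  eo <- expected_outcomes("lam", "selective", p, s)
  rb <- rollback(build_selective(p, "lam", s))
  expect_equal(eo$cost, rb$cost, tolerance = 0)
  expect_equal(eo$effect, rb$effect, tolerance = 0)
  expect_error(expected_outcomes("nope", "treat_all", p, s),
               "unknown diagnostic")
})

test_that("equal mortalities and survivor utilities null the increment", {
  p <- base_params(); s <- st_plain()
  p <- set_parameter(p, "p_death_untreated_tb", 0.135)
  p <- set_parameter(p, "p_death_suspect_no_tb", 0.135)
  p <- set_parameter(p, "dw_tb_hiv", 0.1)
  p <- set_parameter(p, "dw_hiv_art", 0.1)
  ta <- rollback(build_treat_all(p, "xpert", s))
  soc <- rollback(build_selective(p, "xpert", s))
  expect_equal(ta$effect - soc$effect, 0, tolerance = 1e-12)
})
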