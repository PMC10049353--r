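test_that("range-less parameters take multiplicative +/-10% excursions", {
  p <- base_params(); s <- st_plain()
  entry <- one_way("p_death_treated_tb", p, s, "xpert")
  expect_equal(entry$low_value, 0.1215, tolerance = 1e-12)
  expect_equal(entry$high_value, 0.1485, tolerance = 1e-12)
  # tabulated ranges take precedence
  entry2 <- one_way("p_death_untreated_tb", p, s, "xpert")
  expect_equal(entry2$low_value, 0.75, tolerance = 0)
  expect_equal(entry2$high_value, 1.00, tolerance = 0)
  # clipping at the probability boundary
  p2 <- set_parameter(p, "p_death_treated_tb", 0.95)
  r <- sensitivity_range(p2, "p_death_treated_tb")
  expect_equal(unname(r["high"]), 1.0, tolerance = 0)
})

test_that("zero-width ranges yield zero spread with a warning", {
  p <- base_params(); s <- st_plain()
  p$ranges$p_resistance <- c(0.065, 0.065)
  expect_warning(entry <- one_way("p_resistance", p,
                                  st_delayed("success_mediated"), "xpert"),
                 "degenerate")
  expect_identical(entry$spread, 0)
})

test_that("parameters off every path have exactly zero spread", {
  p <- base_params(); s <- st_plain()  # mortality_direct
  for (nm in c("p_treatment_success_sensitive", "p_resistance")) {
    entry <- one_way(nm, p, s, "xpert")
    expect_identical(entry$spread, 0)
  }
  # treatment cost cannot move a pure-QALY outcome
  expect_identical(one_way("cost_tb_treatment", p, s, "xpert")$spread, 0)
  # untreated-TB mortality with full delayed uptake: the untreated branch
  # has zero mass, mirroring "no contribution to the QALY difference"
  p_full <- base_params(); p_full$p_delayed_empiric <- 1
  entry <- one_way("p_death_untreated_tb", p_full, st_delayed(), "combined")
  expect_identical(entry$spread, 0)
})

test_that("the base-case outcome agrees with the direct CEA computation", {
  p <- base_params(); s <- st_delayed("success_mediated")
  entry <- one_way("p_resistance", p, s, "combined")
  tab <- compare_all(p, s, diagnostics = "combined")
  expect_equal(entry$outcome_at_base, tab$incremental_effect,
               tolerance = 1e-15)
  entry_icer <- one_way("p_resistance", p, s, "combined", outcome = "icer")
  expect_equal(entry_icer$outcome_at_base, tab$icer, tolerance = 1e-15)
})

test_that("spread is symmetric under relabeling of the excursion ends", {
  p <- base_params(); s <- st_delayed()
  e <- one_way("p_death_suspect_no_tb", p, s, "lam")
  expect_equal(e$spread, abs(e$outcome_at_low - e$outcome_at_high),
               tolerance = 0)
  expect_true(e$spread >= 0)
})

test_that("outcome moves monotonically across each tabulated range", {
  p <- base_params(); s <- st_delayed("success_mediated")
  for (nm in names(p$ranges)) {
    r <- p$ranges[[nm]]
    grid <- seq(r[1], r[2], length.out = 7)
    vals <- vapply(grid, function(v)
      icer(rollback(build_treat_all(set_parameter(p, nm, v), "combined", s)),
           rollback(build_selective(set_parameter(p, nm, v), "combined", s)))$incremental_effect,
      numeric(1))
    expect_true(all(diff(vals) >= -1e-12) || all(diff(vals) <= 1e-12),
                label = paste("monotone incremental effect in", nm))
  }
})

test_that("tornado rows are sorted by spread with alphabetical tie-breaks", {
  p <- base_params(); s <- st_delayed("success_mediated")
  tor <- tornado(p, s, "combined")
  expect_true(all(diff(tor$spread) <= 1e-15))
  ties <- split(tor$parameter, round(tor$spread, 15))
  for (grp in ties) expect_identical(as.character(grp), sort(grp))
  expect_identical(tor$rank, seq_len(nrow(tor)))
  # all zero-width ranges: all spreads zero, stable name order
  p0 <- p
  for (nm in unique(c(names(p0$ranges), "prevalence_tb")))
    p0$ranges[[nm]] <- rep(get_parameter(p0, nm), 2)
  suppressWarnings(tor0 <- tornado(p0, s, "combined",
    parameters = c("prevalence_tb", names(base_params()$ranges))))
  expect_true(all(tor0$spread == 0))
  expect_identical(tor0$parameter, sort(tor0$parameter))
})
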