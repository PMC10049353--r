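# Incremental cost-effectiveness analysis and the calibration harness.

#' Incremental cost-effectiveness of treat-all versus standard of care
#'
#' Computes `incremental_cost = C1 - C0` and
#' `incremental_effect = E1 - E0` (treat-all minus standard of care) and
#' their ratio, the ICER, in USD per QALY. Dominance short-circuits the
#' ratio: `treat_all_dominant` when the intervention is no costlier and at
#' least as effective (not both increments zero), `soc_dominant` in the
#' mirror case, `equivalent` when both increments are exactly zero. The
#' stored ICER is exact (unrounded); [format()] and the CSV writers round
#' to cents for display.
#'
#' @param treat_all,soc [payoff()]s for the two arms.
#' @param strategy_name Label carried into the result.
#' @return An object of class `ce_result`: a list with fields
#'   `strategy_name`, `cost_treat_all`, `cost_soc`, `effect_treat_all`,
#'   `effect_soc`, `incremental_cost`, `incremental_effect`, `icer`
#'   (`NA` unless defined), `dominance`.
#' @examples
#' icer(payoff(212.42, 0.77), payoff(50.72, 0.69), "xpert")
#' @export
icer <- function(treat_all, soc, strategy_name = "strategy") {
  stopifnot(inherits(treat_all, "payoff"), inherits(soc, "payoff"))
  dc <- treat_all$cost - soc$cost
  de <- treat_all$effect - soc$effect
  dominance <- "none"
  ratio <- NA_real_
  if (dc == 0 && de == 0) {
    dominance <- "equivalent"
  } else if (dc <= 0 && de >= 0) {
    dominance <- "treat_all_dominant"
  } else if (dc >= 0 && de <= 0) {
    dominance <- "soc_dominant"
  } else {
    ratio <- dc / de
  }
  structure(list(strategy_name = strategy_name,
                 cost_treat_all = treat_all$cost, cost_soc = soc$cost,
                 effect_treat_all = treat_all$effect,
                 effect_soc = soc$effect,
                 incremental_cost = dc, incremental_effect = de,
                 icer = ratio, dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s\n", x$strategy_name))
  cat(sprintf("  treat-all: cost %.2f, effect %.6f\n",
              x$cost_treat_all, x$effect_treat_all))
  cat(sprintf("  SOC:       cost %.2f, effect %.6f\n",
              x$cost_soc, x$effect_soc))
  cat(sprintf("  increments: dC %.4f, dE %.6f\n",
              x$incremental_cost, x$incremental_effect))
  if (x$dominance == "none")
    cat(sprintf("  ICER: %.2f USD/QALY\n", x$icer))
  else
    cat("  dominance:", x$dominance, "\n")
  invisible(x)
}

ce_result_row <- function(x) {
  data.frame(strategy = x$strategy_name,
             cost_treat_all = x$cost_treat_all, cost_soc = x$cost_soc,
             effect_treat_all = x$effect_treat_all,
             effect_soc = x$effect_soc,
             incremental_cost = x$incremental_cost,
             incremental_effect = x$incremental_effect,
             icer = x$icer, dominance = x$dominance)
}

#' Cost-effectiveness comparison across all diagnostic strategies
#'
#' Evaluates both arms for each diagnostic strategy and applies [icer()].
#' Ordering is deterministic: LAM, Xpert, combined (then any further
#' diagnostics in their declaration order).
#'
#' @param params A [parameter_set()].
#' @param structure A [structure_config()].
#' @param diagnostics Strategy names; defaults to all diagnostics in
#'   `params`, with the canonical three first.
#' @return Data frame with one row per strategy: per-arm cost/effect,
#'   increments, ICER and dominance.
#' @export
compare_all <- function(params, structure,
                        diagnostics = NULL) {
  stopifnot(inherits(params, "tb_params"),
            inherits(structure, "structure_config"))
  if (is.null(diagnostics)) {
    canonical <- c("lam", "xpert", "combined")
    have <- names(params$diagnostics)
    diagnostics <- c(intersect(canonical, have), setdiff(have, canonical))
  }
  rows <- lapply(diagnostics, function(d) {
    res <- icer(expected_outcomes(d, "treat_all", params, structure),
                expected_outcomes(d, "selective", params, structure),
                strategy_name = d)
    ce_result_row(res)
  })
  do.call(rbind, rows)
}

#' Reference results targeted by the calibration harness
#'
#' The reported incremental effectiveness (QALYs, printed to 2 decimal
#' places) and ICER (USD/QALY, printed to cents) of immediate empiric
#' therapy versus standard of care for each diagnostic strategy. These are
#' calibration *inputs*: the harness searches the structural space for the
#' configuration whose outputs come closest to them.
#'
#' @return Named list (per strategy) of lists with `delta_e` and `icer`.
#' @export
default_calibration_targets <- function() {
  list(lam = list(delta_e = 0.05, icer = 2683.19),
       xpert = list(delta_e = 0.08, icer = 2021.26),
       combined = list(delta_e = 0.03, icer = 4269.73))
}

# Mean relative error of a configuration against the targets. Incremental
# effectiveness is compared after rounding to its printed precision
# (2 d.p.); the ICER is compared unrounded.
calibration_residuals <- function(params, structure, targets) {
  cmp <- compare_all(params, structure, diagnostics = names(targets))
  rows <- lapply(names(targets), function(s) {
    r <- cmp[cmp$strategy == s, ]
    t <- targets[[s]]
    de_model <- round(r$incremental_effect, 2)
    icer_model <- r$icer
    data.frame(
      strategy = s,
      quantity = c("delta_e", "icer"),
      model = c(de_model, icer_model),
      target = c(t$delta_e, t$icer),
      rel_error = c(abs(de_model - t$delta_e) / abs(t$delta_e),
                    abs(icer_model - t$icer) / abs(t$icer)))
  })
  do.call(rbind, rows)
}

structural_grid <- function() {
  grid <- expand.grid(
    sepsis_dw_applied = c(TRUE, FALSE),
    soc_delayed_empiric = c(TRUE, FALSE),
    mortality_mode = c("mortality_direct", "success_mediated"),
    stringsAsFactors = FALSE)
  # documented iteration order: mortality mode outermost, defaults first
  grid[order(match(grid$mortality_mode,
                   c("mortality_direct", "success_mediated")),
             !grid$soc_delayed_empiric,
             !grid$sepsis_dw_applied), , drop = FALSE]
}

#' Calibrate the structural unknowns of the model
#'
#' The published model leaves three structural choices and the time horizon
#' unstated. The harness exhaustively evaluates the structural grid
#' (mortality mode x delayed-empiric x sepsis-disability-weight) crossed
#' with a coarse horizon grid, then refines the horizon on a fine grid
#' (step `refine_step`) around each configuration's best coarse value, and
#' returns the configuration minimizing the mean relative error over the
#' six targets (incremental effectiveness compared at 2 decimal places, its
#' printed precision; ICERs unrounded). Deterministic: ties keep the first
#' configuration in the documented iteration order.
#'
#' @param params A [parameter_set()]; `horizon_years` is overridden by the
#'   search.
#' @param targets As [default_calibration_targets()].
#' @param horizons Coarse horizon grid in years.
#' @param refine_step Fine-grid step for horizon refinement.
#' @param arm_shared_diagnostic_cost Fixed (not searched): the trial runs
#'   diagnostics in both arms.
#' @return An object of class `tb_calibration`: `structure`, `horizon`,
#'   `params` (with the calibrated horizon), `objective`, `residuals`
#'   (per-target data frame), `results` (the [compare_all()] table at the
#'   optimum), `attained` (TRUE iff every target is matched at its printed
#'   precision), and `search` (per-configuration best objective).
#' @export
calibrate <- function(params,
                      targets = default_calibration_targets(),
                      horizons = seq(0.25, 2, by = 0.25),
                      refine_step = 0.001,
                      arm_shared_diagnostic_cost = TRUE) {
  stopifnot(inherits(params, "tb_params"), length(targets) > 0,
            length(horizons) > 0)
  grid <- structural_grid()
  objective_at <- function(structure, h) {
    p <- params
    p$horizon_years <- h
    mean(calibration_residuals(p, structure, targets)$rel_error)
  }
  best <- NULL
  search_rows <- list()
  for (i in seq_len(nrow(grid))) {
    structure <- structure_config(
      mortality_mode = grid$mortality_mode[i],
      soc_delayed_empiric = grid$soc_delayed_empiric[i],
      sepsis_dw_applied = grid$sepsis_dw_applied[i],
      arm_shared_diagnostic_cost = arm_shared_diagnostic_cost)
    coarse <- vapply(horizons, function(h) objective_at(structure, h),
                     numeric(1))
    h0 <- horizons[which.min(coarse)]
    step <- if (length(horizons) > 1L) min(diff(sort(horizons))) else 0.25
    fine <- seq(max(refine_step, h0 - step), h0 + step, by = refine_step)
    fine_obj <- vapply(fine, function(h) objective_at(structure, h),
                       numeric(1))
    j <- which.min(fine_obj)
    search_rows[[i]] <- data.frame(
      mortality_mode = structure$mortality_mode,
      soc_delayed_empiric = structure$soc_delayed_empiric,
      sepsis_dw_applied = structure$sepsis_dw_applied,
      horizon = fine[j], objective = fine_obj[j])
    if (is.null(best) || fine_obj[j] < best$objective)
      best <- list(structure = structure, horizon = fine[j],
                   objective = fine_obj[j])
  }
  cal_params <- params
  cal_params$horizon_years <- best$horizon
  residuals <- calibration_residuals(cal_params, best$structure, targets)
  # "attained" = every target reproduced at its printed precision
  de <- residuals$quantity == "delta_e"
  attained <- all(abs(residuals$model[de] - residuals$target[de]) < 5e-3) &&
    all(abs(round(residuals$model[!de], 2) - residuals$target[!de]) < 5e-3)
  structure(list(structure = best$structure, horizon = best$horizon,
                 params = cal_params, objective = best$objective,
                 residuals = residuals,
                 results = compare_all(cal_params, best$structure,
                                       diagnostics = names(targets)),
                 attained = attained,
                 search = do.call(rbind, search_rows)),
            class = "tb_calibration")
}

#' @export
print.tb_calibration <- function(x, ...) {
  cat("<tb_calibration>\n  best configuration: ")
  print(x$structure)
  cat(sprintf("  horizon: %.3f years | mean relative error: %.4f | targets attained: %s\n",
              x$horizon, x$objective, x$attained))
  print(x$residuals, row.names = FALSE)
  invisible(x)
}
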