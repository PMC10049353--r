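# Builders for the six model arms: treat-all and selective treatment
# (standard of care), for each of the three diagnostic strategies.

HEALTH_STATES <- c("dead", "survived_tb_treated", "survived_tb_untreated",
                   "survived_no_tb")

state_dw <- function(state, params) {
  switch(state,
    survived_tb_treated = params$dw_tb_treatment,
    survived_tb_untreated = params$dw_tb_hiv,
    survived_no_tb = params$dw_hiv_art,
    stop("no disability weight for state '", state, "'"))
}

#' QALYs accrued in a terminal health state
#'
#' Death yields 0 QALYs. A survivor accrues
#' `(1 - dw_state) * horizon_years`; when the structure applies the acute
#' sepsis decrement, the first `acute_days` of the horizon are additionally
#' weighted by `(1 - dw_severe_sepsis)` (multiplicative combination of
#' concurrent disability weights, the standard convention for comorbid
#' states):
#' `(1 - dw_state) * ((horizon - a) + (1 - dw_sepsis) * a)` with
#' `a = min(acute_days / 365, horizon)`.
#'
#' @param state One of `"dead"`, `"survived_tb_treated"`,
#'   `"survived_tb_untreated"`, `"survived_no_tb"`.
#' @param params A [parameter_set()].
#' @param structure A [structure_config()].
#' @return QALYs (numeric scalar).
#' @examples
#' p <- default_parameters()
#' s <- structure_config(sepsis_dw_applied = FALSE)
#' qaly_for_state("survived_no_tb", p, s)  # (1 - 0.053) * 1 = 0.947
#' @export
qaly_for_state <- function(state, params, structure) {
  state <- match.arg(state, HEALTH_STATES)
  stopifnot(inherits(params, "tb_params"),
            inherits(structure, "structure_config"))
  if (state == "dead") return(0)
  dw <- state_dw(state, params)
  h <- params$horizon_years
  if (!structure$sepsis_dw_applied) return((1 - dw) * h)
  a <- min(params$acute_days / 365, h)
  (1 - dw) * ((h - a) + (1 - params$dw_severe_sepsis) * a)
}

# Terminal node helper: leaf carries the total path cost.
leaf <- function(state, cost, params, structure) {
  terminal_node(state, cost, qaly_for_state(state, params, structure))
}

# Mortality/outcome subtree for a patient with TB who receives anti-TB
# treatment. `success` is the rifampin-susceptible success probability of
# the regimen actually delivered (immediate empiric vs SOC-initiated).
treated_outcome_subtree <- function(params, structure, cost, success,
                                    label = "treated_tb") {
  if (structure$mortality_mode == "mortality_direct") {
    chance_node(label,
      c(die = params$p_death_treated_tb,
        survive = 1 - params$p_death_treated_tb),
      list(leaf("dead", cost, params, structure),
           leaf("survived_tb_treated", cost, params, structure)))
  } else {
    susceptible <- chance_node(paste0(label, "_susceptible"),
      c(success = success, failure = 1 - success),
      list(leaf("survived_tb_treated", cost, params, structure),
           leaf("dead", cost, params, structure)))
    resistant <- chance_node(paste0(label, "_resistant"),
      c(die = params$p_death_untreated_tb,
        survive = 1 - params$p_death_untreated_tb),
      list(leaf("dead", cost, params, structure),
           leaf("survived_tb_untreated", cost, params, structure)))
    chance_node(label,
      c(susceptible = 1 - params$p_resistance,
        resistant = params$p_resistance),
      list(susceptible, resistant))
  }
}

#' Treated-TB outcome subtree
#'
#' Exposes the mortality factorization used for treated TB patients. In
#' `mortality_direct` mode death occurs with the directly estimated
#' `p_death_treated_tb`; in `success_mediated` mode patients split by
#' rifampin resistance, susceptible patients survive with the regimen's
#' success probability, and resistant patients follow untreated-TB
#' mortality. Exactly one mode applies per run.
#'
#' @param params A [parameter_set()].
#' @param structure A [structure_config()].
#' @param cost Total path cost carried into the leaves.
#' @param success Success probability of the delivered regimen in
#'   rifampin-susceptible TB; defaults to the immediate-empiric value.
#' @return A chance `tree_node`.
#' @export
treated_outcome <- function(params, structure, cost = 0,
                            success = params$p_treatment_success_sensitive) {
  stopifnot(inherits(params, "tb_params"),
            inherits(structure, "structure_config"))
  treated_outcome_subtree(params, structure, cost, success)
}

# outcome subtree for a patient without TB (suspect mortality applies)
no_tb_subtree <- function(params, structure, cost, label = "no_tb") {
  chance_node(label,
    c(die = params$p_death_suspect_no_tb,
      survive = 1 - params$p_death_suspect_no_tb),
    list(leaf("dead", cost, params, structure),
         leaf("survived_no_tb", cost, params, structure)))
}

get_diagnostic <- function(params, diagnostic) {
  d <- params$diagnostics[[diagnostic]]
  if (is.null(d))
    stop("unknown diagnostic '", diagnostic, "'; available: ",
         paste(names(params$diagnostics), collapse = ", "))
  d
}

#' Build the treat-all (immediate empiric therapy) arm
#'
#' Every patient incurs the diagnostic cost (when
#' `arm_shared_diagnostic_cost` is set, as in the trial) plus the anti-TB
#' treatment cost. Patients branch on true TB status at
#' `prevalence_tb`: TB patients follow the treated-outcome subtree under
#' the *immediate-empiric* success parameter; non-TB patients die with
#' `p_death_suspect_no_tb` or survive as `survived_no_tb`.
#'
#' @param params A [parameter_set()].
#' @param diagnostic Name of a diagnostic in `params$diagnostics`.
#' @param structure A [structure_config()].
#' @return A chance-rooted `tree_node` (passes [validate_tree()]).
#' @export
build_treat_all <- function(params, diagnostic, structure) {
  stopifnot(inherits(params, "tb_params"),
            inherits(structure, "structure_config"))
  d <- get_diagnostic(params, diagnostic)
  base_cost <- params$cost_tb_treatment +
    if (structure$arm_shared_diagnostic_cost) d$unit_cost else 0
  chance_node(paste0("treat_all_", diagnostic),
    c(tb = params$prevalence_tb, no_tb = 1 - params$prevalence_tb),
    list(treated_outcome_subtree(params, structure, base_cost,
                                 params$p_treatment_success_sensitive),
         no_tb_subtree(params, structure, base_cost)))
}

#' Build the selective-treatment (standard of care) arm
#'
#' Every patient is tested (diagnostic cost always incurred in this arm).
#' The test-result branch uses the marginal positivity
#' [prob_test_positive()]; posterior TB status within each result branch
#' uses [ppv()] and `1 - `[npv()]. Test-positive patients receive anti-TB
#' treatment (SOC success parameter). False positives keep non-TB suspect
#' mortality and utility, with treatment cost added. Missed TB patients
#' either (when `soc_delayed_empiric`) survive the initial untreated period
#' with the delayed-empiric uptake probability and then receive treatment,
#' or follow untreated-TB mortality.
#'
#' @inheritParams build_treat_all
#' @return A chance-rooted `tree_node` (passes [validate_tree()]).
#' @export
build_selective <- function(params, diagnostic, structure) {
  stopifnot(inherits(params, "tb_params"),
            inherits(structure, "structure_config"))
  d <- get_diagnostic(params, diagnostic)
  diag_cost <- d$unit_cost
  treat_cost <- params$cost_tb_treatment
  prev <- params$prevalence_tb
  p_pos <- prob_test_positive(prev, d)
  soc_success <- params$p_treatment_success_soc

  # test-positive branch: treatment delivered on confirmation
  if (p_pos > 0) {
    p_tb_pos <- ppv(prev, d)
    positive <- chance_node("tb_given_positive",
      c(tb = p_tb_pos, no_tb = 1 - p_tb_pos),
      list(treated_outcome_subtree(params, structure,
                                   diag_cost + treat_cost, soc_success,
                                   label = "confirmed_tb"),
           no_tb_subtree(params, structure, diag_cost + treat_cost,
                         label = "false_positive")))
  } else {
    positive <- leaf("survived_no_tb", diag_cost, params, structure)
  }

  # test-negative branch: missed TB vs true negative
  untreated_tb <- chance_node("untreated_tb",
    c(die = params$p_death_untreated_tb,
      survive = 1 - params$p_death_untreated_tb),
    list(leaf("dead", diag_cost, params, structure),
         leaf("survived_tb_untreated", diag_cost, params, structure)))
  missed <- if (structure$soc_delayed_empiric) {
    p_up <- effective_delayed_uptake(params)
    chance_node("delayed_empiric",
      c(delayed_treatment = p_up, no_treatment = 1 - p_up),
      list(treated_outcome_subtree(params, structure,
                                   diag_cost + treat_cost, soc_success,
                                   label = "delayed_treated_tb"),
           untreated_tb))
  } else {
    untreated_tb
  }
  if (p_pos < 1) {
    p_tb_neg <- prob_disease_given_negative(prev, d)
    negative <- chance_node("tb_given_negative",
      c(missed_tb = p_tb_neg, true_negative = 1 - p_tb_neg),
      list(missed,
           no_tb_subtree(params, structure, diag_cost,
                         label = "true_negative")))
  } else {
    negative <- missed
  }

  chance_node(paste0("selective_", diagnostic),
    c(test_positive = p_pos, test_negative = 1 - p_pos),
    list(positive, negative))
}

#' Build the full decision model for one diagnostic strategy
#'
#' @inheritParams build_treat_all
#' @return A decision-rooted `tree_node` with alternatives `treat_all` and
#'   `selective`.
#' @export
build_decision_root <- function(params, diagnostic, structure) {
  decision_node(paste0("strategy_", diagnostic),
    list(treat_all = build_treat_all(params, diagnostic, structure),
         selective = build_selective(params, diagnostic, structure)))
}

#' Expected cost and effectiveness of one arm
#'
#' Builds the requested arm and rolls it back; deterministic given inputs.
#'
#' @param diagnostic Diagnostic strategy name.
#' @param arm `"treat_all"` or `"selective"`.
#' @param params A [parameter_set()].
#' @param structure A [structure_config()].
#' @return A [payoff()].
#' @export
expected_outcomes <- function(diagnostic, arm = c("treat_all", "selective"),
                              params, structure) {
  arm <- match.arg(arm)
  tree <- if (arm == "treat_all") build_treat_all(params, diagnostic, structure)
          else build_selective(params, diagnostic, structure)
  rollback(tree)
}
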