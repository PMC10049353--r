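# Model parameter container and the structural configuration.

SCALAR_PARAMS <- c(
  "prevalence_tb",
  "p_treatment_success_sensitive", "p_treatment_success_soc",
  "p_resistance",
  "p_death_treated_tb", "p_death_untreated_tb", "p_death_suspect_no_tb",
  "p_delayed_empiric",
  "dw_tb_hiv", "dw_tb_treatment", "dw_hiv_art", "dw_severe_sepsis",
  "cost_tb_treatment", "horizon_years", "acute_days")

# parameters bounded to [0,1] (probabilities and disability weights)
FRACTION_PARAMS <- grep("^(p_|dw_|prevalence)", SCALAR_PARAMS, value = TRUE)

#' Names of the scalar model parameters
#'
#' @return Character vector of the scalar (non-diagnostic) parameter names
#'   of a [parameter_set()].
#' @export
scalar_parameter_names <- function() SCALAR_PARAMS

#' Model parameter set
#'
#' All probabilities, disability weights, costs and diagnostic profiles of
#' the decision model, each probability optionally carrying a
#' `(low, high)` sensitivity range. Fractions are stored in \[0, 1\].
#'
#' @param prevalence_tb TB prevalence among HIV-positive sepsis admissions.
#' @param p_treatment_success_sensitive Treatment success in
#'   rifampin-susceptible TB under the *immediate empiric* regimen (the
#'   novel-intervention efficacy parameter, anchored on preliminary data).
#' @param p_treatment_success_soc Treatment success in rifampin-susceptible
#'   TB when therapy starts after diagnostic confirmation or as delayed
#'   empiric rescue in the standard-of-care arm; defaults to the same base
#'   value, but is a distinct parameter so the two regimens' efficacies can
#'   be varied independently.
#' @param p_resistance Probability of rifampin resistance.
#' @param p_death_treated_tb Mortality among TB patients given anti-TB
#'   treatment (direct estimate; used in `mortality_direct` mode).
#' @param p_death_untreated_tb Mortality among patients with untreated TB.
#' @param p_death_suspect_no_tb Mortality among sepsis suspects without TB.
#' @param p_delayed_empiric Probability that a missed-TB patient in the
#'   standard-of-care arm survives to receive delayed empiric therapy;
#'   `NA` (the default) derives it as `1 - p_death_suspect_no_tb`, tying it
#'   to survival at day 7 among suspects without TB confirmation.
#' @param dw_tb_hiv,dw_tb_treatment,dw_hiv_art,dw_severe_sepsis Disability
#'   weights (0 = full health, 1 = death-equivalent) for TB with HIV,
#'   TB under treatment, HIV on ART, and the acute severe-sepsis phase.
#' @param cost_tb_treatment Cost of a course of anti-TB treatment, USD.
#' @param horizon_years Model time horizon in years over which survivor
#'   QALYs accrue; a structural unknown resolved by [calibrate()].
#' @param acute_days Length in days of the acute sepsis phase over which
#'   `dw_severe_sepsis` applies (when the structure enables it).
#' @param diagnostics Named list of [diagnostic_profile()]s; the case study
#'   uses `lam`, `xpert` and `combined`.
#' @param ranges Named list of `c(low, high)` sensitivity ranges keyed by
#'   parameter name; parameters without a range fall under the
#'   multiplicative +/-10% rule in one-way sensitivity analysis.
#' @return An object of class `tb_params` (a named list).
#' @seealso [default_parameters()], [set_parameter()], [load_parameters()]
#' @export
parameter_set <- function(prevalence_tb,
                          p_treatment_success_sensitive,
                          p_treatment_success_soc = p_treatment_success_sensitive,
                          p_resistance,
                          p_death_treated_tb,
                          p_death_untreated_tb,
                          p_death_suspect_no_tb,
                          p_delayed_empiric = NA_real_,
                          dw_tb_hiv, dw_tb_treatment, dw_hiv_art,
                          dw_severe_sepsis,
                          cost_tb_treatment,
                          horizon_years = 1.0,
                          acute_days = 7,
                          diagnostics = list(),
                          ranges = list()) {
  p <- structure(
    list(prevalence_tb = prevalence_tb,
         p_treatment_success_sensitive = p_treatment_success_sensitive,
         p_treatment_success_soc = p_treatment_success_soc,
         p_resistance = p_resistance,
         p_death_treated_tb = p_death_treated_tb,
         p_death_untreated_tb = p_death_untreated_tb,
         p_death_suspect_no_tb = p_death_suspect_no_tb,
         p_delayed_empiric = p_delayed_empiric,
         dw_tb_hiv = dw_tb_hiv, dw_tb_treatment = dw_tb_treatment,
         dw_hiv_art = dw_hiv_art, dw_severe_sepsis = dw_severe_sepsis,
         cost_tb_treatment = cost_tb_treatment,
         horizon_years = horizon_years, acute_days = acute_days,
         diagnostics = diagnostics, ranges = ranges),
    class = "tb_params")
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  for (nm in FRACTION_PARAMS) {
    v <- p[[nm]]
    if (nm == "p_delayed_empiric" && is.na(v)) next
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must lie in [0,1], got ", v)
  }
  if (!is.numeric(p$cost_tb_treatment) || p$cost_tb_treatment < 0)
    stop("cost_tb_treatment must be >= 0")
  if (!is.numeric(p$horizon_years) || p$horizon_years <= 0)
    stop("horizon_years must be > 0")
  if (!is.numeric(p$acute_days) || p$acute_days < 0)
    stop("acute_days must be >= 0")
  for (d in p$diagnostics)
    if (!inherits(d, "diagnostic_profile"))
      stop("diagnostics must be diagnostic_profile objects")
  for (nm in names(p$ranges)) {
    r <- p$ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L])
      stop("range for '", nm, "' must be c(low, high) with low <= high")
    base <- get_parameter(p, nm)
    if (base < r[1L] || base > r[2L])
      stop("base value of '", nm, "' (", base,
           ") lies outside its range [", r[1L], ", ", r[2L], "]")
  }
  invisible(p)
}

#' Base-case parameter set of the TB-sepsis model
#'
#' The tabulated base-case inputs for HIV-positive sepsis admissions in
#' Uganda: diagnostic accuracies and unit costs for urine LAM, sputum Xpert
#' MTB/RIF and their combination; TB prevalence 50%; treatment, resistance
#' and mortality probabilities with literature ranges; disability weights;
#' and the anti-TB treatment cost. The combined strategy uses tabulated
#' literature estimates of joint accuracy (not an independence
#' composition), and its diagnostic cost is the sum of both tests.
#'
#' @return A [parameter_set()].
#' @examples
#' p <- default_parameters()
#' p$diagnostics$xpert
#' @export
default_parameters <- function() {
  parameter_set(
    prevalence_tb = 0.50,
    p_treatment_success_sensitive = 0.80,
    p_resistance = 0.065,
    p_death_treated_tb = 0.135,
    p_death_untreated_tb = 0.90,
    p_death_suspect_no_tb = 0.20,
    dw_tb_hiv = 0.399,
    dw_tb_treatment = 0.1,
    dw_hiv_art = 0.053,
    dw_severe_sepsis = 0.31,
    cost_tb_treatment = 195,
    horizon_years = 1.0,
    acute_days = 7,
    diagnostics = list(
      lam = diagnostic_profile("lam", 0.53, 0.96, 4.19),
      xpert = diagnostic_profile("xpert", 0.42, 0.99, 17.42),
      combined = diagnostic_profile("combined", 0.635, 0.99,
                                    4.19 + 17.42)),
    ranges = list(
      p_treatment_success_sensitive = c(0.66, 0.92),
      p_resistance = c(0.04, 0.15),
      p_death_untreated_tb = c(0.75, 1.00),
      p_death_suspect_no_tb = c(0.07, 0.30)))
}

# Addressable parameter names: scalars plus per-diagnostic fields
# ("xpert_sensitivity", "lam_unit_cost", ...).
diag_param_names <- function(params) {
  unlist(lapply(names(params$diagnostics), function(d)
    paste0(d, "_", c("sensitivity", "specificity", "unit_cost"))))
}

#' Read or replace a single named parameter
#'
#' Addresses scalar parameters by name and diagnostic fields as
#' `"<diagnostic>_sensitivity"`, `"<diagnostic>_specificity"` or
#' `"<diagnostic>_unit_cost"`. `set_parameter()` returns a modified copy:
#' parameter sets are treated as immutable, and sensitivity analysis
#' rebuilds trees from modified copies rather than mutating nodes.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @param value Replacement value (for `set_parameter`).
#' @return `get_parameter()`: the numeric value. `set_parameter()`: a new
#'   `tb_params`.
#' @export
get_parameter <- function(params, name) {
  stopifnot(inherits(params, "tb_params"))
  if (name %in% SCALAR_PARAMS) return(params[[name]])
  m <- regmatches(name, regexec("^(.*)_(sensitivity|specificity|unit_cost)$", name))[[1L]]
  if (length(m) == 3L && m[2L] %in% names(params$diagnostics))
    return(params$diagnostics[[m[2L]]][[m[3L]]])
  stop("unknown parameter: '", name, "'")
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "tb_params"), is.numeric(value),
            length(value) == 1L)
  if (name %in% SCALAR_PARAMS) {
    params[[name]] <- as.numeric(value)
  } else {
    m <- regmatches(name, regexec("^(.*)_(sensitivity|specificity|unit_cost)$", name))[[1L]]
    if (length(m) == 3L && m[2L] %in% names(params$diagnostics)) {
      params$diagnostics[[m[2L]]][[m[3L]]] <- as.numeric(value)
    } else {
      stop("unknown parameter: '", name, "'")
    }
  }
  # ranges may legitimately exclude the new value during excursions; check
  # everything else
  saved <- params$ranges
  params$ranges <- list()
  validate_parameters(params)
  params$ranges <- saved
  params
}

#' Sensitivity bounds for one parameter
#'
#' Returns the tabulated `(low, high)` range when one exists; otherwise
#' applies the multiplicative +/-10% rule (`base * 0.9`, `base * 1.1`),
#' clipped to \[0, 1\] for probabilities and disability weights. An
#' additive +/-0.1 variant is available for exploration.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @param pct10 Either `"multiplicative"` (default) or `"additive"`.
#' @return Named numeric vector `c(low = , high = )`.
#' @export
sensitivity_range <- function(params, name,
                              pct10 = c("multiplicative", "additive")) {
  pct10 <- match.arg(pct10)
  base <- get_parameter(params, name)
  if (!is.null(params$ranges[[name]])) {
    r <- params$ranges[[name]]
    return(c(low = r[1L], high = r[2L]))
  }
  r <- if (pct10 == "multiplicative") c(base * 0.9, base * 1.1)
       else c(base - 0.1, base + 0.1)
  bounded <- name %in% FRACTION_PARAMS ||
    grepl("_(sensitivity|specificity)$", name)
  if (bounded) r <- pmin(pmax(r, 0), 1)
  else r <- pmax(r, 0)
  c(low = r[1L], high = r[2L])
}

#' @export
print.tb_params <- function(x, ...) {
  cat("<tb_params> TB-sepsis decision model parameters\n")
  for (nm in SCALAR_PARAMS)
    cat(sprintf("  %-30s %s%s\n", nm, format(x[[nm]]),
                if (!is.null(x$ranges[[nm]]))
                  sprintf("  [%.3g, %.3g]", x$ranges[[nm]][1L],
                          x$ranges[[nm]][2L]) else ""))
  for (d in x$diagnostics)
    cat(sprintf("  diagnostic %-10s sens %.3f spec %.3f USD %.2f\n",
                d$name, d$sensitivity, d$specificity, d$unit_cost))
  invisible(x)
}

#' Structural configuration of the decision model
#'
#' The published description of this model leaves several structural
#' choices open; this object makes each one explicit so runs are
#' reproducible and the calibration harness can search over them.
#'
#' @param mortality_mode `"mortality_direct"`: treated TB patients die with
#'   the directly estimated `p_death_treated_tb`. `"success_mediated"`:
#'   treated patients first split by rifampin resistance; susceptible
#'   patients survive with the regimen's success probability, resistant
#'   patients follow untreated-TB mortality.
#' @param soc_delayed_empiric Should missed-TB patients in the
#'   standard-of-care arm be able to reach delayed empiric therapy after
#'   surviving the initial untreated period (WHO-style rescue at day 3-5)?
#' @param sepsis_dw_applied Apply the severe-sepsis disability weight as an
#'   acute-phase decrement to all survivors.
#' @param arm_shared_diagnostic_cost Charge the diagnostic workup in both
#'   arms (true in the trial context, where diagnostics run in both arms).
#' @return An object of class `structure_config`.
#' @export
structure_config <- function(mortality_mode = c("mortality_direct",
                                                "success_mediated"),
                             soc_delayed_empiric = TRUE,
                             sepsis_dw_applied = TRUE,
                             arm_shared_diagnostic_cost = TRUE) {
  mortality_mode <- match.arg(mortality_mode)
  stopifnot(is.logical(soc_delayed_empiric), length(soc_delayed_empiric) == 1L,
            is.logical(sepsis_dw_applied), length(sepsis_dw_applied) == 1L,
            is.logical(arm_shared_diagnostic_cost),
            length(arm_shared_diagnostic_cost) == 1L)
  structure(list(mortality_mode = mortality_mode,
                 soc_delayed_empiric = soc_delayed_empiric,
                 sepsis_dw_applied = sepsis_dw_applied,
                 arm_shared_diagnostic_cost = arm_shared_diagnostic_cost),
            class = "structure_config")
}

#' @export
print.structure_config <- function(x, ...) {
  cat("<structure_config>",
      x$mortality_mode,
      if (x$soc_delayed_empiric) "| delayed empiric" else "| no delayed empiric",
      if (x$sepsis_dw_applied) "| sepsis DW on" else "| sepsis DW off",
      if (x$arm_shared_diagnostic_cost) "| shared diagnostic cost"
      else "| SOC-only diagnostic cost", "\n")
  invisible(x)
}

# Effective delayed-empiric uptake: explicit value if set, else tied to
# surviving the initial period as a suspect without confirmed TB.
effective_delayed_uptake <- function(params) {
  if (is.na(params$p_delayed_empiric))
    1 - params$p_death_suspect_no_tb
  else
    params$p_delayed_empiric
}
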