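# One-way deterministic sensitivity analysis (tornado diagram).

outcome_value <- function(params, structure, diagnostic,
                          outcome = c("delta_qaly", "icer")) {
  outcome <- match.arg(outcome)
  res <- icer(expected_outcomes(diagnostic, "treat_all", params, structure),
              expected_outcomes(diagnostic, "selective", params, structure),
              strategy_name = diagnostic)
  if (outcome == "delta_qaly") res$incremental_effect else res$icer
}

#' One-way excursion of a single parameter
#'
#' Evaluates the chosen outcome (incremental effectiveness in QALYs, or the
#' ICER) with one parameter at the low and high end of its sensitivity
#' range, all other parameters held at base. Parameters with a tabulated
#' range use it; the rest use the multiplicative +/-10% rule (see
#' [sensitivity_range()]). Because every chance node in this model is
#' binary, the sibling branch absorbs the complement of the varied
#' probability automatically (complement-branch renormalization).
#'
#' @param parameter Parameter name (scalar or `"<diagnostic>_sensitivity"`
#'   style, see [get_parameter()]).
#' @param params A [parameter_set()].
#' @param structure A [structure_config()].
#' @param diagnostic Diagnostic strategy evaluated.
#' @param outcome `"delta_qaly"` (default, matching the published tornado)
#'   or `"icer"`.
#' @param pct10 Rule for range-less parameters, see [sensitivity_range()].
#' @return One-row data frame: `parameter`, `base_value`, `low_value`,
#'   `high_value`, `outcome_at_base`, `outcome_at_low`, `outcome_at_high`,
#'   `spread` (= `|outcome_at_high - outcome_at_low|`).
#' @export
one_way <- function(parameter, params, structure, diagnostic,
                    outcome = c("delta_qaly", "icer"),
                    pct10 = c("multiplicative", "additive")) {
  outcome <- match.arg(outcome)
  base <- get_parameter(params, parameter)
  r <- sensitivity_range(params, parameter, pct10 = match.arg(pct10))
  if (r["low"] == r["high"])
    warning("degenerate (zero-width) range for '", parameter,
            "': spread is 0")
  at <- function(v)
    outcome_value(set_parameter(params, parameter, v), structure,
                  diagnostic, outcome)
  out_low <- at(r[["low"]])
  out_high <- at(r[["high"]])
  data.frame(parameter = parameter, base_value = base,
             low_value = r[["low"]], high_value = r[["high"]],
             outcome_at_base = outcome_value(params, structure, diagnostic,
                                             outcome),
             outcome_at_low = out_low, outcome_at_high = out_high,
             spread = abs(out_high - out_low))
}

default_tornado_parameters <- function(params, diagnostic) {
  c(setdiff(scalar_parameter_names(),
            c("p_delayed_empiric", "horizon_years", "acute_days")),
    paste0(diagnostic, "_", c("sensitivity", "specificity", "unit_cost")))
}

#' Tornado table: one-way sensitivity analysis over all parameters
#'
#' Runs [one_way()] for every varied parameter and orders the rows by
#' descending spread (ties broken alphabetically by parameter name, for
#' reproducibility). The derived delayed-empiric uptake and the structural
#' horizon/acute-phase settings are not varied by default: the uptake moves
#' with `p_death_suspect_no_tb`, and the horizon is a calibration quantity,
#' not a sampled parameter.
#'
#' @inheritParams one_way
#' @param parameters Parameter names to vary; default: all base-case
#'   scalar inputs plus the evaluated diagnostic's sensitivity, specificity
#'   and unit cost.
#' @return Data frame of [one_way()] rows plus a `rank` column.
#' @export
tornado <- function(params, structure, diagnostic,
                    outcome = c("delta_qaly", "icer"),
                    parameters = default_tornado_parameters(params, diagnostic),
                    pct10 = c("multiplicative", "additive")) {
  outcome <- match.arg(outcome)
  pct10 <- match.arg(pct10)
  rows <- do.call(rbind, lapply(parameters, one_way, params = params,
                                structure = structure,
                                diagnostic = diagnostic, outcome = outcome,
                                pct10 = pct10))
  rows <- rows[order(-rows$spread, rows$parameter), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Plot a tornado diagram
#'
#' Horizontal bars from `outcome_at_low` to `outcome_at_high` per
#' parameter, widest on top, with a vertical base-case line. Requires
#' ggplot2.
#'
#' @param entries Output of [tornado()].
#' @param top Show at most this many parameters.
#' @return A ggplot object.
#' @export
plot_tornado <- function(entries, top = 12L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tornado() needs the ggplot2 package")
  e <- utils::head(entries[order(-entries$spread), , drop = FALSE], top)
  e$parameter <- factor(e$parameter, levels = rev(e$parameter))
  e$lo <- pmin(e$outcome_at_low, e$outcome_at_high)
  e$hi <- pmax(e$outcome_at_low, e$outcome_at_high)
  ggplot2::ggplot(e) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = e$outcome_at_base[1L],
                        linetype = "dashed") +
    ggplot2::labs(x = "outcome", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
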