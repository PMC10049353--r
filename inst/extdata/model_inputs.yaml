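# Base-case inputs of the TB-sepsis decision model (HIV-positive sepsis
# admissions, Ugandan trial perspective). Probabilities are written as
# percentages (units: percent); disability weights, costs and times are
# taken as written.
units: percent
parameters:
  prevalence_tb: 50
  p_treatment_success_sensitive: {value: 80, low: 66, high: 92}
  p_resistance: {value: 6.5, low: 4, high: 15}
  p_death_treated_tb: 13.5
  p_death_untreated_tb: {value: 90, low: 75, high: 100}
  p_death_suspect_no_tb: {value: 20, low: 7, high: 30}
  dw_tb_hiv: 0.399
  dw_tb_treatment: 0.1
  dw_hiv_art: 0.053
  dw_severe_sepsis: 0.31
  cost_tb_treatment: 195
  horizon_years: 1.0
  acute_days: 7
diagnostics:
  lam: {sensitivity: 53, specificity: 96, unit_cost: 4.19}
  xpert: {sensitivity: 42, specificity: 99, unit_cost: 17.42}
  # combined accuracy is a tabulated literature estimate of the joint
  # strategy, not an independence composition; its cost is both tests
  combined: {sensitivity: 63.5, specificity: 99, unit_cost: 21.61}
# reported incremental effectiveness (QALYs) and ICER (USD/QALY) of
# immediate empiric therapy vs standard of care: calibration targets
reference_results:
  lam: {delta_e: 0.05, icer: 2683.19}
  xpert: {delta_e: 0.08, icer: 2021.26}
  combined: {delta_e: 0.03, icer: 4269.73}
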