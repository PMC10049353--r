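---
title: "The TB-sepsis decision model: structure, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TB-sepsis decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbsepcea)
```

## The question and the model

Among HIV-positive adults admitted with sepsis in high-burden settings,
roughly half harbour tuberculosis, sputum is hard to obtain, and the
available rapid diagnostics (urine LAM, sputum Xpert MTB/RIF) miss a
substantial fraction of cases. The model compares two strategies over a
short, trial-like horizon:

* **treat all** — every patient receives immediate empiric anti-TB
  therapy on top of standard antimicrobials;
* **selective treatment** (standard of care) — anti-TB therapy starts
  only on a positive diagnostic result, or as delayed empiric rescue for
  patients who fail to improve.

Each strategy is a decision tree. The treat-all arm branches on true TB
status at the prevalence; TB patients enter a treated-outcome subtree and
non-TB patients face suspect (non-TB sepsis) mortality. The
standard-of-care arm branches first on the test result using the marginal
positivity $P(+) = p\,Se + (1-p)(1-Sp)$, then on posterior TB status
within each result branch using PPV and $1-\mathrm{NPV}$. Conditioning on
the test result first, or on disease status first, are mathematically
equivalent factorizations of the same joint distribution; the test suite
checks the law of total probability
$\mathrm{PPV}\cdot P(+) + (1-\mathrm{NPV})\cdot P(-) = p$ on a dense
grid, so either factorization could be used without changing expected
values.

Terminal payoffs are two-dimensional: cost in USD and effectiveness in
QALYs. Costs are accumulated *along the path into the leaf* (every leaf
carries the total cost of its path), which makes the rollback exactly a
path-probability-weighted sum of leaf payoffs and avoids double-counting
per-node increments. Death scores 0 QALYs; a survivor scores
$(1-dw)\times h$ for horizon $h$ and state disability weight $dw$. When
the acute sepsis decrement is enabled, the first $a = \min(7/365, h)$
years are additionally weighted by $(1-dw_{sepsis})$, multiplicatively —
the standard convention for concurrent disabilities:
$(1-dw)\,[(h-a) + (1-dw_{sepsis})\,a]$.

## Parameters

All parameters ship in `inst/extdata/model_inputs.yaml` and as
`default_parameters()`. Probabilities and weights are dimensionless
fractions in $[0,1]$; costs are USD per patient; the horizon is in years.

| parameter | base (range) | meaning |
|---|---|---|
| `prevalence_tb` | 0.50 | TB prevalence among HIV-positive sepsis admissions |
| `lam` sens/spec | 0.53 / 0.96, USD 4.19 | urine LAM accuracy and unit cost |
| `xpert` sens/spec | 0.42 / 0.99, USD 17.42 | sputum Xpert accuracy (folding in specimen obtainability) and cost |
| `combined` sens/spec | 0.635 / 0.99, USD 21.61 | tabulated joint LAM+Xpert accuracy; cost = both tests |
| `p_treatment_success_sensitive` | 0.80 (0.66–0.92) | success of the *immediate empiric* regimen in rifampin-susceptible TB |
| `p_treatment_success_soc` | 0.80 | success of diagnosis-triggered / delayed treatment |
| `p_resistance` | 0.065 (0.04–0.15) | rifampin resistance |
| `p_death_treated_tb` | 0.135 | mortality on anti-TB treatment (direct estimate) |
| `p_death_untreated_tb` | 0.90 (0.75–1.00) | mortality with untreated TB |
| `p_death_suspect_no_tb` | 0.20 (0.07–0.30) | mortality of sepsis suspects without TB |
| `p_delayed_empiric` | derived | uptake of delayed empiric rescue; defaults to `1 - p_death_suspect_no_tb` |
| `dw_tb_hiv`, `dw_tb_treatment`, `dw_hiv_art`, `dw_severe_sepsis` | 0.399, 0.1, 0.053, 0.31 | disability weights |
| `cost_tb_treatment` | USD 195 | one course of anti-TB treatment |
| `horizon_years` | 1.0 | QALY accrual horizon (calibrated; see below) |
| `acute_days` | 7 | length of the acute sepsis phase |

Two choices deserve explanation:

* **Combined-test accuracy** is the tabulated literature estimate
  (63.5%/99%), *not* an independence composition of LAM and Xpert —
  conditional independence fails for these tests (it would imply
  sensitivity $1 - 0.47\times0.58 = 0.727$). `compose_either_positive()`
  exists for exploration only. The combined diagnostic cost defaults to
  the sum of both tests (both are performed) and is configurable.
* **Two treatment-success parameters.** The efficacy of the immediate
  empiric regimen is the novel, preliminary-data-anchored quantity under
  study, and it is the parameter that carries the tabulated 66–92% range;
  treatment initiated on diagnostic confirmation (or as delayed rescue)
  in the standard-of-care arm is conventional therapy and carries its own
  parameter, equal at base. Keeping them distinct lets the one-way
  sensitivity analysis vary the intervention's efficacy without silently
  moving the comparator arm; with a single shared parameter the
  excursions would cancel almost completely in the QALY difference, and
  the success rate could never rank among the influential parameters —
  contradicting its clinically expected dominance, which the tornado here
  reproduces.

## Structural unknowns and calibration

Four structural readings are left open by the published description of
this analysis, and each is an explicit `structure_config()` field rather
than a hidden assumption:

* `mortality_mode` — treated-TB mortality either read directly
  (`mortality_direct`, the 13.5% estimate, the default) or mediated by
  resistance and treatment success (`success_mediated`, in which
  susceptible patients survive with the regimen's success probability and
  resistant patients follow untreated mortality; base-case death
  probability $0.935(1-0.80)+0.065\cdot0.90 = 0.2455$). Both readings are
  provided because the tabulated inputs support both; neither is asserted
  as *the* published structure.
* `soc_delayed_empiric` — whether missed-TB patients can reach delayed
  empiric therapy after surviving the initial untreated period (WHO-style
  rescue after 3–5 days of failed antibiotics). Default on. The uptake
  probability is tied by default to day-7 survival of suspects without
  confirmed TB (`1 - p_death_suspect_no_tb`), which is also what makes
  that survival parameter contribute to the QALY difference; with full
  uptake (`p_delayed_empiric = 1`) untreated-TB mortality sits on a
  zero-mass path and contributes exactly nothing.
* `sepsis_dw_applied` — whether the acute severe-sepsis decrement applies
  to all survivors (every enrollee has sepsis). Default on; calibration
  may switch it off.
* `arm_shared_diagnostic_cost` — in the trial both arms run the
  diagnostics, so both arms are charged for them by default; a policy
  analysis can drop the cost from the treat-all arm. Standard-of-care
  antibiotics and hospitalization costs are set to zero in both arms:
  they cancel in the increments and are absent from the tabulated inputs.

The QALY horizon is the single largest unstated quantity, so it is an
explicit parameter (default 1 year) searched by `calibrate()`:
structural grid (mortality mode × delayed-empiric × sepsis decrement)
crossed with horizons 0.25–2.0 in steps of 0.25, then a fine grid (step
0.001) around each configuration's best coarse value. The objective is
the mean relative error over the six reference targets (three strategies
× incremental effectiveness and ICER), with incremental effectiveness
compared after rounding to its printed precision (2 d.p.) and ICERs
compared unrounded; ties keep the first configuration in the documented
iteration order, so the result is deterministic. The calibration report
carries per-target residuals. A structural limit is worth stating: in
every tree in this search space the incremental effectiveness factors as
$p\,(1-Se)\times\delta$ with $\delta$ independent of the diagnostic, so
the *ratios* of incremental effectiveness across strategies are pinned at
$(1-Se)$ ratios, and no configuration can drive all six residuals to
zero simultaneously; `calibrate()$attained` records honestly whether the
targets were met, and the test suite asserts the report rather than
forcing a fit.

```{r calibrate, eval = FALSE}
params <- load_parameters(system.file("extdata", "model_inputs.yaml",
                                      package = "tbsepcea"))
cal <- calibrate(params, targets = attr(params, "reference_results"))
cal$residuals
```

## Sensitivity analysis conventions

`one_way()`/`tornado()` vary one parameter at a time between its
tabulated low and high; parameters without a range use the
multiplicative ±10% rule (`base × 0.9`, `base × 1.1`), clipped to
$[0,1]$ for probabilities and weights (an additive variant exists behind
a flag). Every chance node in this model is binary, so the sibling
branch absorbs the complement of a varied probability automatically —
the usual complement-branch renormalization. The default outcome is the
QALY difference between arms; an ICER tornado is available by flag.
Entries are ranked by descending spread with alphabetical tie-breaks, so
tables are reproducible. The derived delayed-uptake parameter and the
structural horizon are not varied by default: the former moves with
`p_death_suspect_no_tb`, the latter is a calibration quantity.

## The microsimulation oracle and what passing tests mean

`simulate_cohort()` walks individual patients through a validated tree,
sampling every chance node independently, with an explicit seed and a
fixed traversal order, so cohorts are byte-for-byte reproducible and
cohort means are unbiased estimators of the rollback values.
`perturb_parameters()` draws parameter sets uniformly within the
tabulated ranges (±10% where none exists, independently across
parameters — no correlation structure is available to impose). Together
they fuzz the analytic pipeline: the test suite checks rollback against
exhaustive path enumeration to $10^{-12}$ relative and against
microsimulation means within four standard errors at $n = 10^5$ patients
for all six arms across 50 perturbed parameter sets, plus targeted
checks at $n = 2\times10^5$. These sizes keep the default suite within a
couple of minutes while leaving Monte-Carlo error far below any decision
threshold.

The synthetic cohorts emulate *the model's own* branching process — they
validate the arithmetic, not the epidemiology. They do not contain
measurement error, time-to-event structure, correlated parameters,
covariates, loss to follow-up, or any deviation from the tree's
conditional independencies, so passing these tests says nothing about
how well the tree itself represents real TB-sepsis cohorts.

## Numerical choices

* Chance-node probabilities must sum to 1 within $10^{-9}$ and are
  stored exactly as given — never silently renormalized, so
  transcription errors surface as validation failures.
* Trees are immutable after building; sensitivity analysis and
  calibration rebuild from modified parameter copies.
* Expected values are plain double-precision sums; currency is rounded
  to cents only at display/serialization, never in stored values.
* ICER edge cases: dominance by increment signs; equal effects with
  unequal costs yield no ratio and dominance by cost sign; exact
  equality of both increments is flagged `equivalent`.
* Degenerate inputs: zero-width sensitivity ranges produce zero-spread
  entries with a warning; a perfect test collapses the selective arm to
  the treat-all arm in effectiveness; prevalence 0/1 collapse the
  corresponding branches and the Bayes layer raises informative errors
  where posteriors are undefined.

## Known limitations

Short-horizon cohort tree only: no Markov/state-transition structure, no
discounting, no half-cycle correction, no probabilistic sensitivity
analysis or EVPI, no budget-impact layer; CD4 strata, ART transitions,
second-line pathways for rifampin-resistant TB and newer assays
(e.g. FujiLAM) are out of scope. The reference-value calibration is an
honest search with reported residuals, not a guarantee of reproduction —
see the structural limit above.
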