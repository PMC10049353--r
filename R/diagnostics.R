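#' Diagnostic test profile
#'
#' Sensitivity and specificity here are *operational*: for sputum Xpert they
#' fold together assay accuracy and the ability to obtain a diagnostic
#' specimen, as tabulated for hospitalized HIV-positive cohorts.
#'
#' @param name Test name (e.g. `"xpert"`).
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @param unit_cost Per-test cost in USD, >= 0.
#' @return An object of class `diagnostic_profile`.
#' @examples
#' diagnostic_profile("xpert", 0.42, 0.99, 17.42)
#' @export
diagnostic_profile <- function(name, sensitivity, specificity, unit_cost) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(sensitivity = sensitivity, specificity = specificity))
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("sensitivity/specificity must lie in [0,1]")
  if (!is.numeric(unit_cost) || unit_cost < 0)
    stop("unit_cost must be >= 0")
  structure(list(name = name, sensitivity = as.numeric(sensitivity),
                 specificity = as.numeric(specificity),
                 unit_cost = as.numeric(unit_cost)),
            class = "diagnostic_profile")
}

#' @export
print.diagnostic_profile <- function(x, ...) {
  cat(sprintf("<diagnostic> %s: sens %.3f, spec %.3f, USD %.2f\n",
              x$name, x$sensitivity, x$specificity, x$unit_cost))
  invisible(x)
}

check_prevalence <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must be a single number in [0,1]")
  invisible(prevalence)
}

#' Marginal probability of a positive test
#'
#' `P(+) = prevalence * sens + (1 - prevalence) * (1 - spec)`.
#'
#' @param prevalence Disease prevalence in the tested population, \[0, 1\].
#' @param test A [diagnostic_profile()].
#' @return Fraction in \[0, 1\].
#' @examples
#' xpert <- diagnostic_profile("xpert", 0.42, 0.99, 17.42)
#' prob_test_positive(0.5, xpert)  # 0.215
#' @export
prob_test_positive <- function(prevalence, test) {
  check_prevalence(prevalence)
  stopifnot(inherits(test, "diagnostic_profile"))
  prevalence * test$sensitivity + (1 - prevalence) * (1 - test$specificity)
}

#' Positive predictive value
#'
#' Posterior probability of disease given a positive test, by Bayes' rule:
#' `PPV = prevalence * sens / P(+)`.
#'
#' @inheritParams prob_test_positive
#' @return Fraction in \[0, 1\].
#' @export
ppv <- function(prevalence, test) {
  pp <- prob_test_positive(prevalence, test)
  if (pp <= 0)
    stop("PPV undefined: P(test positive) is 0 for test '", test$name, "'")
  prevalence * test$sensitivity / pp
}

#' Negative predictive value and the missed-disease probability
#'
#' `NPV = (1 - prevalence) * spec / (1 - P(+))`. The complement
#' `P(disease | test-) = 1 - NPV` parameterizes the missed-TB branch of the
#' standard-of-care arm; [prob_disease_given_negative()] exposes it
#' directly.
#'
#' @inheritParams prob_test_positive
#' @return Fraction in \[0, 1\].
#' @export
npv <- function(prevalence, test) {
  pp <- prob_test_positive(prevalence, test)
  if (pp >= 1)
    stop("NPV undefined: P(test negative) is 0 for test '", test$name, "'")
  (1 - prevalence) * test$specificity / (1 - pp)
}

#' @rdname npv
#' @export
prob_disease_given_negative <- function(prevalence, test) {
  1 - npv(prevalence, test)
}

#' Compose two tests under an either-positive rule assuming independence
#'
#' Exploratory utility only: the case-study's combined LAM+Xpert strategy
#' uses *tabulated* literature estimates of the combination (sens 63.5%,
#' spec 99%), not an independence composition — conditional independence
#' does not hold for these tests (it would imply sens
#' `1 - 0.47 * 0.58 = 0.727`).
#'
#' @param a,b [diagnostic_profile()]s.
#' @param name Name of the composed profile.
#' @return A [diagnostic_profile()] with
#'   `sens = 1 - (1-sens_a)(1-sens_b)`, `spec = spec_a * spec_b`, and the
#'   summed unit cost.
#' @export
compose_either_positive <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  stopifnot(inherits(a, "diagnostic_profile"),
            inherits(b, "diagnostic_profile"))
  diagnostic_profile(
    name,
    1 - (1 - a$sensitivity) * (1 - b$sensitivity),
    a$specificity * b$specificity,
    a$unit_cost + b$unit_cost)
}
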