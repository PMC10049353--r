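# Patient-level Monte-Carlo microsimulation through a decision tree, and
# parameter-set perturbation. The microsimulation is the stochastic oracle
# for the analytic rollback: cohort means are unbiased estimates of the
# expected payoff.

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a patient cohort through a decision tree
#'
#' Each simulated patient walks the tree from the root, sampling every
#' chance node independently; the per-patient record keeps the sequence of
#' branch labels, the terminal state, and that leaf's (cost, QALY) payoff.
#' Sampling is performed cohort-wise per node in a fixed traversal order,
#' so results are byte-for-byte reproducible given `(tree, n, seed)` and
#' independent of any execution plan. The caller's random stream is left
#' untouched.
#'
#' @param tree A validated terminal- or chance-rooted `tree_node`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; required, no implicit entropy.
#' @return An object of class `tb_cohort`: list with `cohort` (data frame:
#'   `patient`, `path`, `state`, `cost`, `qaly`), `summary` (list:
#'   `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`, `state_freq`), and
#'   `n`, `seed`.
#' @export
simulate_cohort <- function(tree, n, seed) {
  stopifnot(inherits(tree, "tree_node"))
  if (tree$kind == "decision")
    stop("simulate one arm at a time, not a decision node")
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("an explicit integer seed is required")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  v <- validate_tree(tree)
  if (nrow(v) > 0L)
    stop("refusing to simulate an invalid tree: ", v$type[1L], " at '",
         v$node[1L], "' (", v$detail[1L], ")")

  cost <- numeric(n); qaly <- numeric(n)
  state <- character(n); path <- character(n)
  rec <- function(node, idx, prefix) {
    if (length(idx) == 0L) return(invisible(NULL))
    if (node$kind == "terminal") {
      cost[idx] <<- node$payoff$cost
      qaly[idx] <<- node$payoff$effect
      state[idx] <<- node$label
      path[idx] <<- if (nzchar(prefix)) paste(prefix, node$label, sep = ">")
                    else node$label
      return(invisible(NULL))
    }
    u <- stats::runif(length(idx))
    edges <- cumsum(node$probs)
    edges[length(edges)] <- 1  # guard the 1e-9 sum tolerance
    branch <- findInterval(u, edges, left.open = TRUE) + 1L
    for (i in seq_along(node$probs)) {
      nm <- names(node$probs)[i]
      rec(node$children[[i]], idx[branch == i],
          if (nzchar(prefix)) paste(prefix, nm, sep = ">") else nm)
    }
    invisible(NULL)
  }
  with_local_seed(seed, rec(tree, seq_len(n), ""))

  se <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else 0
  freq <- table(factor(state, levels = sort(unique(state))))
  structure(list(
    cohort = data.frame(patient = seq_len(n), path = path, state = state,
                        cost = cost, qaly = qaly),
    summary = list(mean_cost = mean(cost), mean_qaly = mean(qaly),
                   se_cost = se(cost), se_qaly = se(qaly),
                   state_freq = freq),
    n = n, seed = as.integer(seed)),
    class = "tb_cohort")
}

#' @export
print.tb_cohort <- function(x, ...) {
  cat(sprintf("<tb_cohort> n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  mean cost %.4f (SE %.4f), mean QALY %.6f (SE %.6f)\n",
              x$summary$mean_cost, x$summary$se_cost,
              x$summary$mean_qaly, x$summary$se_qaly))
  print(x$summary$state_freq)
  invisible(x)
}

PERTURBABLE_PARAMS <- c(
  "prevalence_tb", "p_treatment_success_sensitive",
  "p_treatment_success_soc", "p_resistance", "p_death_treated_tb",
  "p_death_untreated_tb", "p_death_suspect_no_tb",
  "dw_tb_hiv", "dw_tb_treatment", "dw_hiv_art", "dw_severe_sepsis",
  "cost_tb_treatment")

#' Draw a perturbed parameter set
#'
#' Independent uniform draws per parameter, used to fuzz the invariant
#' suites across the parameter space. In `uniform_in_range` mode a
#' parameter with a tabulated range is drawn within it; a parameter
#' without one falls back to +/-10% of base (with a notice). In `pct10`
#' mode every parameter uses +/-10%. Probabilities and disability weights
#' are clipped to \[0, 1\]. Deterministic per seed; draws consume the
#' stream in the fixed parameter order.
#'
#' @param params A [parameter_set()].
#' @param mode `"uniform_in_range"` or `"pct10"`.
#' @param seed Integer seed (required).
#' @param quiet Suppress the fallback notice.
#' @return A new [parameter_set()] (ranges are widened where needed so the
#'   perturbed base stays inside its stored range).
#' @export
perturb_parameters <- function(params,
                               mode = c("uniform_in_range", "pct10"),
                               seed, quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "tb_params"))
  if (missing(seed)) stop("an explicit integer seed is required")
  draws <- with_local_seed(seed, {
    vapply(PERTURBABLE_PARAMS, function(nm) {
      base <- get_parameter(params, nm)
      r <- if (mode == "uniform_in_range" && !is.null(params$ranges[[nm]])) {
        params$ranges[[nm]]
      } else {
        if (mode == "uniform_in_range" && !quiet)
          message("no range for '", nm, "': falling back to +/-10%")
        c(base * 0.9, base * 1.1)
      }
      if (nm %in% FRACTION_PARAMS) r <- pmin(pmax(r, 0), 1)
      stats::runif(1L, r[1L], r[2L])
    }, numeric(1))
  })
  out <- params
  for (nm in PERTURBABLE_PARAMS) {
    out[[nm]] <- unname(draws[[nm]])
    # keep stored ranges consistent with the new base
    if (!is.null(out$ranges[[nm]]))
      out$ranges[[nm]] <- range(c(out$ranges[[nm]], out[[nm]]))
  }
  validate_parameters(out)
  out
}
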