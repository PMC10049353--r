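# Parameter-file schema, report writers, run metadata.
#
# Parameter files are YAML or JSON with the layout:
#
#   units: percent | fraction        # how probabilities are written
#   parameters:                      # scalar inputs; entry = number or
#     prevalence_tb: 50              #   {value:, low:, high:} with a
#     p_resistance: {value: 6.5, low: 4, high: 15}   # sensitivity range
#     dw_tb_hiv: 0.399               # weights/costs are never unit-scaled
#     cost_tb_treatment: 195
#   diagnostics:
#     lam: {sensitivity: 53, specificity: 96, unit_cost: 4.19}
#   structure:                       # optional structure_config block
#     mortality_mode: mortality_direct
#     soc_delayed_empiric: true
#     sepsis_dw_applied: true
#     arm_shared_diagnostic_cost: true
#   reference_results:               # optional calibration targets
#     lam: {delta_e: 0.05, icer: 2683.19}
#
# The `units` key applies to probability fields (prevalence_tb, p_*) and
# diagnostic sensitivity/specificity; disability weights, costs and times
# are always taken as written.

REQUIRED_SCALARS <- c(
  "prevalence_tb", "p_treatment_success_sensitive", "p_resistance",
  "p_death_treated_tb", "p_death_untreated_tb", "p_death_suspect_no_tb",
  "dw_tb_hiv", "dw_tb_treatment", "dw_hiv_art", "dw_severe_sepsis",
  "cost_tb_treatment")

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::read_json(path)
  else yaml::read_yaml(path)
}

unit_scaled <- function(name) grepl("^(p_|prevalence)", name)

#' Load a parameter set from a YAML/JSON file
#'
#' Validates the documented schema: every base-case scalar input and at
#' least one diagnostic are required (a missing field raises an error
#' naming it); probabilities may be written as percentages with
#' `units: percent` and are resolved to fractions; any probability outside
#' \[0, 1\] after unit resolution is a domain error. Optional
#' `reference_results` and `structure` blocks are attached as attributes.
#'
#' @param path Parameter file (`.yaml`/`.yml`/`.json`).
#' @return A [parameter_set()]; attributes `reference_results` and
#'   `structure` when the file carries those blocks.
#' @seealso [write_parameters()], [default_parameters()]; a fixture with
#'   the tabulated base case ships as
#'   `system.file("extdata", "model_inputs.yaml", package = "tbsepcea")`.
#' @export
load_parameters <- function(path) {
  raw <- read_config_file(path)
  units <- raw$units %||% "fraction"
  if (!units %in% c("fraction", "percent"))
    stop("units must be 'fraction' or 'percent', got '", units, "'")
  scale <- if (units == "percent") 0.01 else 1
  pars <- raw$parameters
  if (is.null(pars)) stop("schema error: missing 'parameters' block")
  missing_f <- setdiff(REQUIRED_SCALARS, names(pars))
  if (length(missing_f) > 0L)
    stop("schema error: missing required field(s): ",
         paste(missing_f, collapse = ", "))

  vals <- list(); ranges <- list()
  for (nm in names(pars)) {
    entry <- pars[[nm]]
    s <- if (unit_scaled(nm)) scale else 1
    if (is.list(entry)) {
      if (is.null(entry$value))
        stop("schema error: '", nm, "' entry needs a 'value'")
      vals[[nm]] <- as.numeric(entry$value) * s
      if (!is.null(entry$low) || !is.null(entry$high)) {
        if (is.null(entry$low) || is.null(entry$high))
          stop("schema error: '", nm, "' needs both 'low' and 'high'")
        ranges[[nm]] <- c(as.numeric(entry$low), as.numeric(entry$high)) * s
      }
    } else {
      vals[[nm]] <- as.numeric(entry) * s
    }
    if (unit_scaled(nm) && (vals[[nm]] < 0 || vals[[nm]] > 1))
      stop("domain error: '", nm, "' = ", vals[[nm]],
           " outside [0,1] after unit resolution")
  }

  if (is.null(raw$diagnostics) || length(raw$diagnostics) == 0L)
    stop("schema error: missing 'diagnostics' block")
  diags <- lapply(names(raw$diagnostics), function(dn) {
    d <- raw$diagnostics[[dn]]
    for (f in c("sensitivity", "specificity", "unit_cost"))
      if (is.null(d[[f]]))
        stop("schema error: diagnostic '", dn, "' missing '", f, "'")
    diagnostic_profile(dn, as.numeric(d$sensitivity) * scale,
                       as.numeric(d$specificity) * scale,
                       as.numeric(d$unit_cost))
  })
  names(diags) <- names(raw$diagnostics)

  args <- vals[intersect(names(vals), scalar_parameter_names())]
  params <- do.call(parameter_set,
                    c(args, list(diagnostics = diags, ranges = ranges)))
  if (!is.null(raw$reference_results))
    attr(params, "reference_results") <-
      lapply(raw$reference_results, function(t)
        list(delta_e = as.numeric(t$delta_e), icer = as.numeric(t$icer)))
  if (!is.null(raw$structure))
    attr(params, "structure") <- do.call(structure_config, raw$structure)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter set to a YAML/JSON file
#'
#' Serializes with `units: fraction` (all probabilities as decimals in
#' \[0, 1\], regardless of how they were read), so that
#' `load_parameters(write_parameters(p, f))` is the identity.
#'
#' @param params A [parameter_set()].
#' @param path Output file (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "tb_params"))
  pars <- list()
  for (nm in scalar_parameter_names()) {
    v <- params[[nm]]
    if (nm == "p_delayed_empiric" && is.na(v)) next
    if (!is.null(params$ranges[[nm]]))
      pars[[nm]] <- list(value = v, low = params$ranges[[nm]][1L],
                         high = params$ranges[[nm]][2L])
    else pars[[nm]] <- v
  }
  out <- list(
    units = "fraction",
    parameters = pars,
    diagnostics = lapply(params$diagnostics, function(d)
      list(sensitivity = d$sensitivity, specificity = d$specificity,
           unit_cost = d$unit_cost)))
  rr <- attr(params, "reference_results")
  if (!is.null(rr)) out$reference_results <- rr
  st <- attr(params, "structure")
  if (!is.null(st)) out$structure <- unclass(st)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  else yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Stable content hash of a parameter set
#'
#' Embedded in every output artifact so artifacts from different parameter
#' files never share a hash.
#'
#' @param params A [parameter_set()].
#' @return Character hash.
#' @export
parameter_hash <- function(params) {
  stopifnot(inherits(params, "tb_params"))
  canon <- list(scalars = params[scalar_parameter_names()],
                diagnostics = lapply(params$diagnostics, unclass),
                ranges = params$ranges[order(names(params$ranges))])
  rlang::hash(canon)
}

round_cents <- function(x) round(x, 2)

#' Write the cost-effectiveness table as CSV
#'
#' One row per strategy with per-arm costs and effects, increments, ICER
#' and dominance. Monetary columns and the ICER are rounded to cents at
#' serialization; effectiveness columns are written unrounded.
#'
#' @param cea Output of [compare_all()].
#' @param path Output CSV path.
#' @param params Optional [parameter_set()]; adds a `parameter_hash`
#'   column.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(cea, path, params = NULL) {
  out <- cea
  for (cl in c("cost_treat_all", "cost_soc", "incremental_cost", "icer"))
    out[[cl]] <- round_cents(out[[cl]])
  if (!is.null(params)) out$parameter_hash <- parameter_hash(params)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tornado table as CSV
#'
#' @param entries Output of [tornado()].
#' @param path Output CSV path.
#' @param params Optional [parameter_set()]; adds a `parameter_hash`
#'   column.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(entries, path, params = NULL) {
  out <- entries
  if (!is.null(params)) out$parameter_hash <- parameter_hash(params)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort as CSV and its summary as JSON
#'
#' @param cohort A `tb_cohort` from [simulate_cohort()].
#' @param path Output CSV path.
#' @param summary_path Optional JSON path for the cohort summary.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, summary_path = NULL) {
  stopifnot(inherits(cohort, "tb_cohort"))
  utils::write.csv(cohort$cohort, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    s <- cohort$summary
    jsonlite::write_json(
      list(n = cohort$n, seed = cohort$seed,
           mean_cost = s$mean_cost, mean_qaly = s$mean_qaly,
           se_cost = s$se_cost, se_qaly = s$se_qaly,
           state_freq = as.list(s$state_freq)),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write the calibration report (JSON + human-readable text)
#'
#' @param cal A `tb_calibration` from [calibrate()].
#' @param json_path,txt_path Output paths (either may be `NULL`).
#' @return `json_path`, invisibly.
#' @export
write_calibration_report <- function(cal, json_path, txt_path = NULL) {
  stopifnot(inherits(cal, "tb_calibration"))
  if (!is.null(json_path))
    jsonlite::write_json(
      list(structure = unclass(cal$structure), horizon = cal$horizon,
           objective = cal$objective, attained = cal$attained,
           residuals = cal$residuals, results = cal$results,
           search = cal$search),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(cal)), con)
  }
  invisible(json_path)
}

#' Run metadata for an output directory
#'
#' Records the parameter hash, structural configuration, package version
#' and seed of a run (no timestamp: artifacts must be byte-identical
#' across reruns with the same seed).
#'
#' @param params A [parameter_set()].
#' @param structure A [structure_config()].
#' @param seed Seed used, or `NA` for deterministic runs.
#' @param path Optional JSON output path.
#' @return The metadata list, invisibly if written.
#' @export
run_metadata <- function(params, structure, seed = NA_integer_,
                         path = NULL) {
  meta <- list(
    package = "tbsepcea",
    version = as.character(utils::packageVersion("tbsepcea")),
    parameter_hash = parameter_hash(params),
    structure = unclass(structure),
    seed = if (is.na(seed)) NULL else as.integer(seed))
  if (!is.null(path)) {
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(meta))
  }
  meta
}
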