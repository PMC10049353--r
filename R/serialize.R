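# Tree serialization: a small JSON/YAML dialect with node kind tags.
# Branch probabilities may be stored as numbers or as expressions written
# in terms of named model parameters ("prevalence_tb", "1 - p_resistance"),
# resolved at read time against a parameter set.

#' Convert a tree to a plain (serializable) list
#'
#' @param node A `tree_node`.
#' @return Nested list with `kind` tags, suitable for JSON/YAML output.
#' @export
tree_to_list <- function(node) {
  stopifnot(inherits(node, "tree_node"))
  switch(node$kind,
    terminal = list(kind = "terminal", label = node$label,
                    cost = node$payoff$cost, effect = node$payoff$effect),
    chance = list(kind = "chance", label = node$label,
                  branches = lapply(seq_along(node$probs), function(i)
                    list(name = names(node$probs)[i],
                         prob = node$probs[[i]],
                         child = tree_to_list(node$children[[i]])))),
    decision = list(kind = "decision", label = node$label,
                    alternatives = lapply(seq_along(node$alternatives),
                      function(i)
                        list(name = names(node$alternatives)[i],
                             child = tree_to_list(node$alternatives[[i]])))),
    stop("unknown node kind: ", node$kind))
}

# Evaluate a serialized probability: a number passes through, a character
# expression is evaluated in a restricted environment exposing only the
# scalar parameters (no function calls beyond arithmetic).
resolve_prob <- function(p, params_env) {
  if (is.numeric(p)) return(as.numeric(p))
  if (is.character(p)) {
    expr <- str2lang(p)
    ok_fun <- c("+", "-", "*", "/", "(")
    check <- function(e) {
      if (is.call(e)) {
        if (!as.character(e[[1L]]) %in% ok_fun)
          stop("disallowed function in probability expression: ",
               as.character(e[[1L]]))
        for (a in as.list(e)[-1L]) check(a)
      } else if (!(is.numeric(e) || is.name(e))) {
        stop("disallowed token in probability expression")
      }
    }
    check(expr)
    return(as.numeric(eval(expr, envir = params_env)))
  }
  stop("branch probability must be numeric or a parameter expression")
}

#' Rebuild a tree from its serialized list form
#'
#' @param x Nested list as produced by [tree_to_list()] (or parsed from the
#'   JSON/YAML dialect). Branch `prob` entries may be numbers or character
#'   expressions over the names in `params`.
#' @param params Optional [parameter_set()] (or named list of scalars) used
#'   to resolve probability expressions.
#' @return A `tree_node`.
#' @export
tree_from_list <- function(x, params = NULL) {
  # parent = baseenv() so arithmetic resolves; the whitelist in
  # resolve_prob() keeps expressions to arithmetic over parameter names
  env <- new.env(parent = baseenv())
  if (!is.null(params)) {
    sc <- if (inherits(params, "tb_params")) params[scalar_parameter_names()]
          else params
    for (nm in names(sc))
      if (is.numeric(sc[[nm]])) assign(nm, sc[[nm]], envir = env)
  }
  build <- function(node) {
    switch(node$kind,
      terminal = terminal_node(node$label, node$cost, node$effect),
      chance = {
        probs <- vapply(node$branches, function(b)
          resolve_prob(b$prob, env), numeric(1))
        names(probs) <- vapply(node$branches, function(b)
          as.character(b$name), character(1))
        chance_node(node$label, probs,
                    lapply(node$branches, function(b) build(b$child)))
      },
      decision = {
        alts <- lapply(node$alternatives, function(a) build(a$child))
        names(alts) <- vapply(node$alternatives, function(a)
          as.character(a$name), character(1))
        decision_node(node$label, alts)
      },
      stop("unknown node kind in serialized tree: ", node$kind))
  }
  build(x)
}

#' Write / read a tree as JSON or YAML
#'
#' Format is chosen by file extension (`.json` vs `.yaml`/`.yml`).
#' Numeric probabilities round-trip losslessly.
#'
#' @param node A `tree_node`.
#' @param path Output file.
#' @return `write_tree()` returns `path` invisibly; `read_tree()` returns a
#'   `tree_node`.
#' @export
write_tree <- function(node, path) {
  x <- tree_to_list(node)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 17L)
  }
  invisible(path)
}

#' @rdname write_tree
#' @param params Optional parameter set for probability expressions.
#' @export
read_tree <- function(path, params = NULL) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path)
  else
    yaml::read_yaml(path)
  tree_from_list(x, params = params)
}
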