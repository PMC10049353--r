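#' Two-dimensional payoff (cost, effectiveness)
#'
#' A payoff couples a monetary cost (USD) with an effectiveness measured in
#' quality-adjusted life years (QALYs). Terminal nodes of a decision tree
#' carry payoffs; [rollback()] returns the probability-weighted expectation
#' of both components.
#'
#' @param cost Non-negative, finite cost in USD.
#' @param effect Non-negative, finite effectiveness in QALYs (a death state
#'   carries 0 QALYs).
#' @return An object of class `payoff`: a list with elements `cost` and
#'   `effect`.
#' @examples
#' payoff(195, 0.6)
#' @export
payoff <- function(cost, effect) {
  stopifnot(is.numeric(cost), length(cost) == 1L, is.finite(cost),
            is.numeric(effect), length(effect) == 1L, is.finite(effect))
  if (cost < 0) stop("payoff cost must be >= 0, got ", cost)
  if (effect < 0) stop("payoff effectiveness must be >= 0, got ", effect)
  structure(list(cost = as.numeric(cost), effect = as.numeric(effect)),
            class = "payoff")
}

#' @export
print.payoff <- function(x, ...) {
  cat(sprintf("<payoff> cost = %.4f USD, effect = %.6f QALY\n",
              x$cost, x$effect))
  invisible(x)
}

# Tolerance for chance-node probability sums. Inputs are stored exactly as
# given and never renormalized: silent renormalization would mask parameter
# transcription errors.
PROB_SUM_TOL <- 1e-9

# Guard against malformed (cyclic) structures built from environments;
# ordinary list-built trees cannot exceed this depth in this model.
MAX_TREE_DEPTH <- 64L

#' Terminal node of a decision tree
#'
#' @param label Health-state / leaf name.
#' @param cost,effect Leaf payoff components; the cost is the *total*
#'   accumulated along the path (cost-at-leaf convention), not a per-node
#'   increment.
#' @return A `tree_node` of kind `"terminal"`.
#' @seealso [chance_node()], [decision_node()], [rollback()]
#' @export
terminal_node <- function(label, cost, effect) {
  structure(list(kind = "terminal", label = as.character(label),
                 payoff = payoff(cost, effect)),
            class = "tree_node")
}

#' Chance node of a decision tree
#'
#' Branch probabilities must lie in \[0, 1\] and sum to 1 within 1e-9; they
#' are stored as given (no renormalization).
#'
#' @param label Node name (used in validation messages and path records).
#' @param probs Numeric vector of branch probabilities, optionally named;
#'   names become branch labels in simulated path records.
#' @param children List of child `tree_node`s, same length as `probs`.
#' @return A `tree_node` of kind `"chance"`.
#' @export
chance_node <- function(label, probs, children) {
  stopifnot(is.numeric(probs), is.list(children),
            length(probs) == length(children))
  if (length(probs) < 2L)
    stop("chance node '", label, "' needs >= 2 branches")
  if (is.null(names(probs)))
    names(probs) <- paste0("b", seq_along(probs))
  for (ch in children)
    if (!inherits(ch, "tree_node")) stop("children must be tree_node objects")
  structure(list(kind = "chance", label = as.character(label),
                 probs = probs, children = children),
            class = "tree_node")
}

#' Decision node (root of the model)
#'
#' Holds the mutually exclusive strategies under comparison. In this model a
#' decision node appears only as the root, with the two trial arms as
#' alternatives.
#'
#' @param label Node name.
#' @param alternatives Named list of `tree_node` subtrees, one per strategy.
#' @return A `tree_node` of kind `"decision"`.
#' @export
decision_node <- function(label, alternatives) {
  stopifnot(is.list(alternatives))
  if (length(alternatives) < 2L)
    stop("decision node '", label, "' needs >= 2 alternatives")
  if (is.null(names(alternatives)) || any(!nzchar(names(alternatives))))
    stop("alternatives must be named")
  for (alt in alternatives)
    if (!inherits(alt, "tree_node")) stop("alternatives must be tree_node objects")
  structure(list(kind = "decision", label = as.character(label),
                 alternatives = alternatives),
            class = "tree_node")
}

#' @export
print.tree_node <- function(x, ...) {
  cat("<decision tree node>", x$kind, "-", x$label, "\n")
  invisible(x)
}

#' Validate a decision tree
#'
#' Checks every chance node for probabilities in \[0, 1\] summing to 1
#' within 1e-9, and the structure for acyclicity (depth bound). Violations
#' are returned, not raised.
#'
#' @param tree A `tree_node`.
#' @return A data frame with columns `node`, `type`
#'   (`"range"`/`"sum"`/`"structure"`) and `detail`; zero rows when the tree
#'   is well formed.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "tree_node"))
  out <- list()
  add <- function(node, type, detail)
    out[[length(out) + 1L]] <<- data.frame(node = node, type = type,
                                           detail = detail)
  walk <- function(node, depth) {
    if (depth > MAX_TREE_DEPTH) {
      add(node$label, "structure",
          sprintf("depth exceeds %d: cycle suspected", MAX_TREE_DEPTH))
      return(invisible(NULL))
    }
    if (node$kind == "chance") {
      bad <- node$probs < 0 | node$probs > 1
      if (any(bad))
        add(node$label, "range",
            sprintf("probabilities outside [0,1]: %s",
                    paste(format(node$probs[bad]), collapse = ", ")))
      s <- sum(node$probs)
      if (abs(s - 1) > PROB_SUM_TOL)
        add(node$label, "sum",
            sprintf("branch probabilities sum to %.12g, not 1", s))
      for (ch in node$children) walk(ch, depth + 1L)
    } else if (node$kind == "decision") {
      for (alt in node$alternatives) walk(alt, depth + 1L)
    }
    invisible(NULL)
  }
  walk(tree, 1L)
  if (length(out) == 0L)
    data.frame(node = character(), type = character(), detail = character())
  else
    do.call(rbind, out)
}

#' Expected-value rollback of a decision tree
#'
#' Computes the expected payoff of a terminal- or chance-rooted (sub)tree:
#' a terminal node returns its own payoff; a chance node returns the
#' probability-weighted sum of its children's rollbacks, componentwise for
#' cost and effectiveness. Decision nodes are handled by
#' [evaluate_alternatives()] — no expected-value maximization happens here,
#' because strategy comparison is the job of the cost-effectiveness layer.
#'
#' @param node A terminal or chance `tree_node`.
#' @param validate Run [validate_tree()] first (default `TRUE`); a
#'   violation raises an error naming the offending node.
#' @return A [payoff()].
#' @export
rollback <- function(node, validate = TRUE) {
  stopifnot(inherits(node, "tree_node"))
  if (node$kind == "decision")
    stop("rollback() does not accept a decision node; use evaluate_alternatives()")
  if (validate) {
    v <- validate_tree(node)
    if (nrow(v) > 0L)
      stop("invalid tree: ", v$type[1L], " violation at node '", v$node[1L],
           "' (", v$detail[1L], ")")
  }
  rec <- function(n) {
    if (n$kind == "terminal")
      return(c(n$payoff$cost, n$payoff$effect))
    acc <- c(0, 0)
    for (i in seq_along(n$probs))
      acc <- acc + n$probs[[i]] * rec(n$children[[i]])
    acc
  }
  val <- rec(node)
  payoff(val[1L], val[2L])
}

#' Evaluate every alternative of a decision node
#'
#' @param root A decision `tree_node`.
#' @param validate Passed to [rollback()].
#' @return Named list of [payoff()]s, one per alternative, in the order the
#'   alternatives were declared. No alternative is selected.
#' @export
evaluate_alternatives <- function(root, validate = TRUE) {
  stopifnot(inherits(root, "tree_node"))
  if (root$kind != "decision")
    stop("evaluate_alternatives() needs a decision node, got ", root$kind)
  lapply(root$alternatives, rollback, validate = validate)
}

#' Enumerate all root-to-leaf paths of a tree
#'
#' Exhaustive path expansion: the product of branch probabilities along each
#' path together with the leaf payoff. The expectation
#' \eqn{\sum_{paths} P(path) \cdot payoff(path)} is the independent check of
#' [rollback()]; the implementation here is an explicit-stack traversal,
#' deliberately distinct in shape from the recursive rollback.
#'
#' @param node A terminal or chance `tree_node`.
#' @return Data frame with columns `path` (branch labels joined by `">"`),
#'   `prob`, `cost`, `effect`, `leaf`.
#' @export
enumerate_paths <- function(node) {
  stopifnot(inherits(node, "tree_node"))
  if (node$kind == "decision")
    stop("enumerate_paths() operates on a single arm, not a decision node")
  stack <- list(list(node = node, prob = 1, labels = character()))
  rows <- list()
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    if (n$kind == "terminal") {
      rows[[length(rows) + 1L]] <- data.frame(
        path = paste(c(top$labels, n$label), collapse = ">"),
        prob = top$prob, cost = n$payoff$cost, effect = n$payoff$effect,
        leaf = n$label)
    } else {
      # push in reverse so paths come out in declaration order
      for (i in rev(seq_along(n$probs)))
        stack[[length(stack) + 1L]] <- list(
          node = n$children[[i]],
          prob = top$prob * n$probs[[i]],
          labels = c(top$labels, names(n$probs)[i]))
    }
  }
  do.call(rbind, rows)
}

#' Expected payoff by exhaustive path enumeration
#'
#' @param node A terminal or chance `tree_node`.
#' @return A [payoff()] computed as the path-probability-weighted sum of
#'   leaf payoffs.
#' @export
path_expectation <- function(node) {
  p <- enumerate_paths(node)
  payoff(sum(p$prob * p$cost), sum(p$prob * p$effect))
}
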