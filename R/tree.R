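#' Decision-tree building blocks
#'
#' A cost-utility decision tree is assembled from three node kinds:
#' a single [decision_node()] at the root whose named children are the
#' competing strategies, [chance_node()]s whose branches carry
#' probabilities summing to one, and [terminal_node()]s carrying a
#' cost/utility payoff. Probabilities, costs and utilities may be numeric
#' literals or character expressions over model parameters (a bare
#' parameter name such as `"p_repeat"`, or an arithmetic expression such
#' as `"p_repeat * (1 - reduction)"`), resolved against a parameter
#' binding at evaluation time.
#'
#' Nodes are plain nested lists with class tags; R's copy-on-assign value
#' semantics make cycles impossible by construction.
#'
#' @param cost terminal cost (money, expected to be non-negative);
#'   numeric or character expression.
#' @param utility terminal health-state utility in \[0, 1\]; numeric or
#'   character expression.
#' @param probability branch probability in \[0, 1\]; numeric or character
#'   expression.
#' @param node child node of a branch.
#' @param label optional branch label used in path listings.
#' @param ... for [chance_node()], branches created with [chance_branch()];
#'   for [decision_node()], named child nodes (one per strategy).
#' @return A tree node (list with class `cua_terminal`, `cua_chance` or
#'   `cua_decision`, all inheriting from `cua_node`), or a `cua_branch`.
#' @examples
#' tree <- decision_node(
#'   treat   = terminal_node(cost = 100, utility = 0.9),
#'   observe = chance_node(
#'     chance_branch(0.2, terminal_node(cost = 500, utility = 0.7)),
#'     chance_branch(0.8, terminal_node(cost = 0,   utility = 0.95))
#'   )
#' )
#' rollback(tree, binding = list())
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
terminal_node <- function(cost, utility) {
  structure(list(kind = "terminal", cost = cost, utility = utility),
            class = c("cua_terminal", "cua_node"))
}

#' @rdname tree-nodes
#' @export
chance_branch <- function(probability, node, label = NULL) {
  stopifnot(inherits(node, "cua_node"))
  structure(list(probability = probability, node = node, label = label),
            class = "cua_branch")
}

#' @rdname tree-nodes
#' @export
chance_node <- function(...) {
  branches <- list(...)
  if (length(branches) == 1L && is.list(branches[[1L]]) &&
      !inherits(branches[[1L]], "cua_branch")) {
    branches <- branches[[1L]]
  }
  ok <- vapply(branches, inherits, logical(1), "cua_branch")
  if (!all(ok)) stop("all arguments to chance_node() must be chance_branch() objects")
  structure(list(kind = "chance", branches = branches),
            class = c("cua_chance", "cua_node"))
}

#' @rdname tree-nodes
#' @export
decision_node <- function(...) {
  strategies <- list(...)
  if (length(strategies) == 1L && is.list(strategies[[1L]]) &&
      !inherits(strategies[[1L]], "cua_node")) {
    strategies <- strategies[[1L]]
  }
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    stop("every strategy of a decision_node() must be named")
  ok <- vapply(strategies, inherits, logical(1), "cua_node")
  if (!all(ok)) stop("strategies must be tree nodes")
  structure(list(kind = "decision", strategies = strategies),
            class = c("cua_decision", "cua_node"))
}

## --- quantity resolution -------------------------------------------------

# Parameters a numeric-or-expression quantity refers to (empty for literals).
quantity_vars <- function(x) {
  if (is.numeric(x)) return(character())
  if (!is.character(x) || length(x) != 1L)
    stop("a quantity must be a numeric literal or a single character expression")
  expr <- tryCatch(str2lang(x),
                   error = function(e) stop("cannot parse expression '", x, "'", call. = FALSE))
  all.vars(expr)
}

# Evaluate a quantity against a binding (named list; values may be vectors).
resolve_quantity <- function(x, binding, what = "quantity") {
  if (is.numeric(x)) return(x)
  vars <- quantity_vars(x)
  missing <- setdiff(vars, names(binding))
  if (length(missing))
    stop("missing parameter value", if (length(missing) > 1) "s", " for ",
         what, ": ", paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  eval(str2lang(x), envir = binding, enclos = baseenv())
}

## --- validation ----------------------------------------------------------

#' Validate a decision tree
#'
#' Structural and numeric diagnostics: branch probabilities of every chance
#' node must sum to 1 (within 1e-9), a decision node may appear only at the
#' root, terminal costs must be non-negative and utilities in \[0, 1\].
#' Numeric checks on quantities written as parameter expressions are only
#' performed when a `binding` supplies their values; without one they are
#' skipped, not failed.
#'
#' @param root tree root node.
#' @param binding optional named list of parameter values used to resolve
#'   expression-valued probabilities and payoffs.
#' @return Character vector of diagnostics; `character(0)` when the tree is
#'   well formed. Diagnostics are returned, never thrown.
#' @examples
#' bad <- chance_node(
#'   chance_branch(0.2, terminal_node(0, 1)),
#'   chance_branch(0.7, terminal_node(0, 1))
#' )
#' validate_tree(bad)
#' @export
validate_tree <- function(root, binding = NULL) {
  out <- character()
  note <- function(path, msg) out[[length(out) + 1L]] <<- paste0(path, ": ", msg)

  resolvable <- function(x) {
    is.numeric(x) || (!is.null(binding) &&
      all(quantity_vars(x) %in% names(binding)))
  }
  value_of <- function(x) resolve_quantity(x, binding %||% list())

  walk <- function(node, path, depth) {
    if (depth > 100L) { note(path, "maximum depth exceeded (possible cycle)"); return() }
    if (!inherits(node, "cua_node")) { note(path, "not a tree node"); return() }
    if (inherits(node, "cua_decision")) {
      if (depth > 0L) note(path, "non-root decision node")
      if (!length(node$strategies)) note(path, "decision node has no strategies")
      for (nm in names(node$strategies))
        walk(node$strategies[[nm]], paste0(path, "/", nm), depth + 1L)
    } else if (inherits(node, "cua_chance")) {
      if (!length(node$branches)) { note(path, "chance node has no branches"); return() }
      probs <- lapply(node$branches, `[[`, "probability")
      if (all(vapply(probs, resolvable, logical(1)))) {
        p <- vapply(probs, function(q) value_of(q)[1L], numeric(1))
        if (any(p < -1e-12 | p > 1 + 1e-12))
          note(path, "branch probability outside [0, 1]")
        if (abs(sum(p) - 1) > 1e-9)
          note(path, sprintf("branch probabilities sum to %.12g, not 1", sum(p)))
      }
      for (i in seq_along(node$branches))
        walk(node$branches[[i]]$node, paste0(path, "/b", i), depth + 1L)
    } else if (inherits(node, "cua_terminal")) {
      if (resolvable(node$cost) && any(value_of(node$cost) < 0))
        note(path, "negative terminal cost")
      if (resolvable(node$utility)) {
        u <- value_of(node$utility)
        if (any(u < 0 | u > 1)) note(path, "terminal utility outside [0, 1]")
      }
    } else {
      note(path, paste0("unknown node kind '", node$kind %||% "?", "'"))
    }
  }
  walk(root, "root", 0L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- evaluation ----------------------------------------------------------

# Expected (cost, qaly) of a subtree; vectorised over the binding values.
eval_node <- function(node, binding) {
  if (inherits(node, "cua_terminal")) {
    return(list(cost = resolve_quantity(node$cost, binding, "terminal cost"),
                qaly = resolve_quantity(node$utility, binding, "terminal utility")))
  }
  if (inherits(node, "cua_chance")) {
    probs <- lapply(node$branches, function(b)
      resolve_quantity(b$probability, binding, "branch probability"))
    total <- Reduce(`+`, probs)
    if (max(abs(total - 1)) > 1e-9)
      stop("chance-node branch probabilities do not sum to 1 (max deviation ",
           format(max(abs(total - 1))), ")", call. = FALSE)
    cost <- 0; qaly <- 0
    for (i in seq_along(node$branches)) {
      sub <- eval_node(node$branches[[i]]$node, binding)
      cost <- cost + probs[[i]] * sub$cost
      qaly <- qaly + probs[[i]] * sub$qaly
    }
    return(list(cost = cost, qaly = qaly))
  }
  if (inherits(node, "cua_decision"))
    stop("decision node below the root cannot be rolled back", call. = FALSE)
  stop("unresolved node type", call. = FALSE)
}

#' Evaluate a decision tree by expected-value rollback
#'
#' Computes, for every strategy at the root, the expected cost and expected
#' QALY (probability-weighted terminal utility) by folding the tree from its
#' leaves. Identical, by construction and by test, to aggregating the output
#' of [enumerate_paths()].
#'
#' Binding values may be equal-length vectors, in which case all expected
#' values are computed element-wise in one pass (this is how the
#' probabilistic sensitivity analysis evaluates 10,000 parameter draws).
#'
#' @param root tree root; a decision node, or any node (treated as a single
#'   unnamed strategy `"model"`).
#' @param binding named list mapping parameter names to numeric values
#'   (scalars or equal-length vectors). Every parameter referenced by the
#'   tree must be present; a missing one raises an error naming it.
#' @return Named list (one entry per strategy) of `cua_outcome` objects:
#'   `list(strategy, cost, qaly)`.
#' @seealso [enumerate_paths()] for the path-enumeration oracle,
#'   [compare_strategies()] for the incremental analysis.
#' @export
rollback <- function(root, binding = list()) {
  strategies <- if (inherits(root, "cua_decision")) root$strategies
                else stats::setNames(list(root), "model")
  out <- lapply(names(strategies), function(nm) {
    ev <- eval_node(strategies[[nm]], binding)
    structure(list(strategy = nm, cost = ev$cost, qaly = ev$qaly),
              class = "cua_outcome")
  })
  stats::setNames(out, names(strategies))
}

#' Enumerate root-to-leaf paths of a decision tree
#'
#' Exhaustive listing of every path with its probability (product of branch
#' probabilities along the path), terminal cost and terminal utility. Serves
#' as the independent brute-force oracle for [rollback()]: per strategy,
#' path probabilities sum to 1 and the probability-weighted cost/utility
#' sums equal the rollback expectations.
#'
#' @inheritParams rollback
#' @return `data.frame` with columns `strategy`, `path`, `probability`,
#'   `cost`, `utility` (one row per path; scalar binding assumed).
#' @export
enumerate_paths <- function(root, binding = list()) {
  strategies <- if (inherits(root, "cua_decision")) root$strategies
                else stats::setNames(list(root), "model")
  rows <- list()
  descend <- function(node, strategy, path, prob) {
    if (inherits(node, "cua_terminal")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        strategy = strategy, path = path, probability = prob,
        cost = resolve_quantity(node$cost, binding, "terminal cost"),
        utility = resolve_quantity(node$utility, binding, "terminal utility"),
        stringsAsFactors = FALSE)
    } else if (inherits(node, "cua_chance")) {
      for (i in seq_along(node$branches)) {
        b <- node$branches[[i]]
        p <- resolve_quantity(b$probability, binding, "branch probability")
        descend(b$node, strategy,
                paste0(path, "/", b$label %||% paste0("b", i)), prob * p)
      }
    } else {
      stop("unresolved node type in path enumeration", call. = FALSE)
    }
  }
  for (nm in names(strategies)) descend(strategies[[nm]], nm, nm, 1)
  do.call(rbind, rows)
}

#' @export
print.cua_outcome <- function(x, ...) {
  cat(sprintf("<strategy '%s'>  expected cost %.2f, expected QALY %.4f\n",
              x$strategy, x$cost[1L], x$qaly[1L]))
  invisible(x)
}
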