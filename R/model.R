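#' Assemble a cost-utility model
#'
#' Bundles a decision tree, its parameter specifications and the analysis
#' settings (willingness-to-pay threshold, PSA size, DSA fraction, strategy
#' roles) into one evaluable object.
#'
#' @param parameters list of [parameter_spec()] objects.
#' @param tree tree root (usually a [decision_node()]).
#' @param wtp willingness-to-pay threshold per QALY.
#' @param reference,intervention strategy names used for the incremental
#'   analysis; default to the first and second root strategies.
#' @param n_psa default number of PSA replications.
#' @param dsa_fraction default one-way sensitivity fraction (0.25 = +/-25%).
#' @param label optional model description.
#' @param horizon optional time-horizon label (documentation only; the tree
#'   itself carries no time dimension).
#' @return A `cua_model`.
#' @export
cua_model <- function(parameters, tree, wtp,
                      reference = NULL, intervention = NULL,
                      n_psa = 10000L, dsa_fraction = 0.25,
                      label = NULL, horizon = NULL) {
  ok <- vapply(parameters, inherits, logical(1), "cua_parameter")
  if (!length(parameters) || !all(ok))
    stop("parameters must be a list of parameter_spec() objects")
  names(parameters) <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(names(parameters)))
    stop("duplicate parameter names: ",
         paste(unique(names(parameters)[duplicated(names(parameters))]), collapse = ", "))

  refs <- tree_parameter_refs(tree)
  undefined <- setdiff(refs, names(parameters))
  if (length(undefined))
    stop("tree references undefined parameter",
         if (length(undefined) > 1) "s", ": ",
         paste0("'", undefined, "'", collapse = ", "))

  strategies <- if (inherits(tree, "cua_decision")) names(tree$strategies) else "model"
  reference <- reference %||% strategies[1L]
  intervention <- intervention %||% if (length(strategies) >= 2L) strategies[2L] else strategies[1L]
  if (!all(c(reference, intervention) %in% strategies))
    stop("reference/intervention must name root strategies (",
         paste(strategies, collapse = ", "), ")")

  model <- structure(list(
    parameters = parameters, tree = tree, wtp = wtp,
    reference = reference, intervention = intervention,
    n_psa = as.integer(n_psa), dsa_fraction = dsa_fraction,
    label = label, horizon = horizon), class = "cua_model")

  diags <- validate_tree(tree, base_binding(model))
  if (length(diags))
    stop("tree fails validation:\n", paste("-", diags, collapse = "\n"))
  model
}

# All parameter names referenced anywhere in a tree.
tree_parameter_refs <- function(node) {
  if (inherits(node, "cua_terminal"))
    return(union(quantity_vars(node$cost), quantity_vars(node$utility)))
  if (inherits(node, "cua_chance"))
    return(Reduce(union, lapply(node$branches, function(b)
      union(quantity_vars(b$probability), tree_parameter_refs(b$node))), character()))
  if (inherits(node, "cua_decision"))
    return(Reduce(union, lapply(node$strategies, tree_parameter_refs), character()))
  stop("unknown node type")
}

#' Base-case parameter binding of a model
#'
#' @param model a `cua_model`.
#' @return Named list of every parameter's base value.
#' @export
base_binding <- function(model) {
  stopifnot(inherits(model, "cua_model"))
  lapply(model$parameters, `[[`, "base")
}

#' Base-case analysis of a model
#'
#' Rolls the tree back at every parameter's base value and compares the
#' intervention with the reference strategy at the model's WTP.
#'
#' @param model a `cua_model`.
#' @return A `cua_comparison` (see [compare_strategies()]).
#' @export
base_case <- function(model) {
  out <- rollback(model$tree, base_binding(model))
  compare_strategies(out[[model$reference]], out[[model$intervention]], model$wtp)
}

#' @export
print.cua_model <- function(x, ...) {
  cat(sprintf("<cua_model%s> %d parameters, WTP %g per QALY%s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$parameters), x$wtp,
              if (is.null(x$horizon)) "" else paste0(", horizon ", x$horizon)))
  cat("strategies:", paste(
    if (inherits(x$tree, "cua_decision")) names(x$tree$strategies) else "model",
    collapse = ", "), sprintf("(%s vs %s)\n", x$intervention, x$reference))
  invisible(x)
}
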