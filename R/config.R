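## Model configuration files: a single strict JSON dialect.
##
## Top level: schema_version (1), optional label, parameters (array of
## parameter rows), tree (nested nodes tagged kind = decision | chance |
## terminal), analysis (wtp, n_psa, dsa_fraction, reference, intervention,
## optional seed / wtp_grid / horizon). Unknown keys are rejected and all
## validation errors are reported together, not one at a time.

CONFIG_SCHEMA_VERSION <- 1L

config_keys <- list(
  top       = c("schema_version", "label", "parameters", "tree", "analysis"),
  parameter = c("name", "base", "family", "sd", "dsa_low", "dsa_high",
                "unit_interval", "label"),
  analysis  = c("wtp", "n_psa", "dsa_fraction", "reference", "intervention",
                "seed", "wtp_grid", "horizon"))

#' Read and validate a model configuration
#'
#' Parses a JSON model configuration into a [cua_model()], collecting
#' *all* validation problems — unknown keys, schema-version mismatch,
#' malformed parameter rows, unknown node kinds, dangling parameter
#' references, branch probabilities that do not sum to 1 — before failing
#' with the complete list.
#'
#' @param path path to a JSON configuration file.
#' @return A `cua_model` with attributes `analysis` (the analysis block as
#'   a list, including any `seed`/`wtp_grid`) and `config_md5` (file
#'   checksum for run metadata).
#' @examples
#' cfg <- system.file("extdata", "om85.json", package = "cuatree")
#' model <- read_config(cfg)
#' base_case(model)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse JSON in '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  errs <- character()
  err <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)

  unknown <- setdiff(names(raw), config_keys$top)
  if (length(unknown)) err("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$schema_version)) err("missing schema_version")
  else if (!identical(as.integer(raw$schema_version), CONFIG_SCHEMA_VERSION))
    err("unsupported schema_version ", raw$schema_version,
        " (expected ", CONFIG_SCHEMA_VERSION, ")")

  ## parameters -----------------------------------------------------------
  specs <- list()
  if (is.null(raw$parameters) || !length(raw$parameters)) {
    err("missing or empty 'parameters' block")
  } else {
    for (i in seq_along(raw$parameters)) {
      row <- raw$parameters[[i]]
      bad <- setdiff(names(row), config_keys$parameter)
      if (length(bad))
        err("parameter #", i, ": unknown key(s): ", paste(bad, collapse = ", "))
      spec <- tryCatch(
        parameter_spec(row$name %||% stop("missing name"),
                       row$base %||% stop("missing base"),
                       row$family %||% "fixed",
                       sd = row$sd %||% 0,
                       dsa_low = row$dsa_low, dsa_high = row$dsa_high,
                       unit_interval = row$unit_interval,
                       label = row$label),
        error = function(e) {
          err("parameter #", i, if (!is.null(row$name)) paste0(" ('", row$name, "')"),
              ": ", conditionMessage(e))
          NULL
        })
      if (!is.null(spec)) specs[[length(specs) + 1L]] <- spec
    }
  }

  ## tree -----------------------------------------------------------------
  tree <- NULL
  if (is.null(raw$tree)) err("missing 'tree' block")
  else tree <- node_from_list(raw$tree, "tree", err)

  ## analysis -------------------------------------------------------------
  analysis <- raw$analysis
  if (is.null(analysis)) {
    err("missing 'analysis' block")
  } else {
    bad <- setdiff(names(analysis), config_keys$analysis)
    if (length(bad)) err("analysis: unknown key(s): ", paste(bad, collapse = ", "))
    for (k in c("wtp", "n_psa")) if (is.null(analysis[[k]]))
      err("analysis: missing required key '", k, "'")
  }

  if (length(errs))
    stop("invalid configuration '", path, "':\n",
         paste("-", errs, collapse = "\n"), call. = FALSE)

  model <- tryCatch(
    cua_model(specs, tree, wtp = analysis$wtp,
              reference = analysis$reference, intervention = analysis$intervention,
              n_psa = analysis$n_psa,
              dsa_fraction = analysis$dsa_fraction %||% 0.25,
              label = raw$label, horizon = analysis$horizon),
    error = function(e)
      stop("invalid configuration '", path, "':\n- ", conditionMessage(e),
           call. = FALSE))
  attr(model, "analysis") <- lapply(analysis, function(x)
    if (is.list(x)) unlist(x) else x)
  attr(model, "config_md5") <- unname(tools::md5sum(path))
  model
}

# Recursive JSON -> node conversion; problems are reported through err().
node_from_list <- function(x, path, err) {
  if (!is.list(x) || is.null(x$kind)) {
    err(path, ": node missing 'kind' tag"); return(NULL)
  }
  switch(as.character(x$kind),
    terminal = {
      bad <- setdiff(names(x), c("kind", "cost", "utility"))
      if (length(bad)) err(path, ": unknown key(s): ", paste(bad, collapse = ", "))
      if (is.null(x$cost) || is.null(x$utility)) {
        err(path, ": terminal node needs 'cost' and 'utility'"); return(NULL)
      }
      terminal_node(scalar_quantity(x$cost), scalar_quantity(x$utility))
    },
    chance = {
      bad <- setdiff(names(x), c("kind", "branches"))
      if (length(bad)) err(path, ": unknown key(s): ", paste(bad, collapse = ", "))
      if (is.null(x$branches) || !length(x$branches)) {
        err(path, ": chance node needs a non-empty 'branches' array"); return(NULL)
      }
      branches <- list()
      for (i in seq_along(x$branches)) {
        b <- x$branches[[i]]
        bpath <- paste0(path, "/branches[", i, "]")
        bad <- setdiff(names(b), c("probability", "node", "label"))
        if (length(bad)) err(bpath, ": unknown key(s): ", paste(bad, collapse = ", "))
        if (is.null(b$probability) || is.null(b$node)) {
          err(bpath, ": branch needs 'probability' and 'node'"); next
        }
        child <- node_from_list(b$node, paste0(bpath, "/node"), err)
        if (!is.null(child))
          branches[[length(branches) + 1L]] <-
            chance_branch(scalar_quantity(b$probability), child, label = b$label)
      }
      if (!length(branches)) return(NULL)
      chance_node(branches)
    },
    decision = {
      bad <- setdiff(names(x), c("kind", "strategies"))
      if (length(bad)) err(path, ": unknown key(s): ", paste(bad, collapse = ", "))
      if (is.null(x$strategies) || !length(x$strategies) ||
          is.null(names(x$strategies))) {
        err(path, ": decision node needs named 'strategies'"); return(NULL)
      }
      kids <- list()
      for (nm in names(x$strategies)) {
        child <- node_from_list(x$strategies[[nm]], paste0(path, "/", nm), err)
        if (!is.null(child)) kids[[nm]] <- child
      }
      if (!length(kids)) return(NULL)
      decision_node(kids)
    },
    { err(path, ": unknown node kind '", x$kind, "'"); NULL })
}

scalar_quantity <- function(x) if (is.numeric(x)) x else as.character(x)

# Node -> plain list, inverse of node_from_list (for config round trips).
node_to_list <- function(node) {
  if (inherits(node, "cua_terminal"))
    return(list(kind = "terminal", cost = node$cost, utility = node$utility))
  if (inherits(node, "cua_chance"))
    return(list(kind = "chance", branches = lapply(node$branches, function(b) {
      out <- list(probability = b$probability, node = node_to_list(b$node))
      if (!is.null(b$label)) out$label <- b$label
      out
    })))
  if (inherits(node, "cua_decision"))
    return(list(kind = "decision", strategies = lapply(node$strategies, node_to_list)))
  stop("unknown node type")
}

#' Write a model configuration
#'
#' Serializes a `cua_model` to the JSON dialect read by [read_config()];
#' `read_config(write_config(model, path))` reproduces the model.
#'
#' @param model a `cua_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(model, path) {
  stopifnot(inherits(model, "cua_model"))
  params <- lapply(model$parameters, function(p) {
    row <- list(name = p$name, base = p$base, family = p$family)
    if (p$family != "fixed") row$sd <- p$sd
    if (!is.null(p$dsa_low)) { row$dsa_low <- p$dsa_low; row$dsa_high <- p$dsa_high }
    if (!identical(p$unit_interval, p$family == "beta"))
      row$unit_interval <- p$unit_interval
    if (!is.null(p$label)) row$label <- p$label
    row
  })
  cfg <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    label = model$label,
    parameters = unname(params),
    tree = node_to_list(model$tree),
    analysis = list(wtp = model$wtp, n_psa = model$n_psa,
                    dsa_fraction = model$dsa_fraction,
                    reference = model$reference,
                    intervention = model$intervention,
                    horizon = model$horizon))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
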