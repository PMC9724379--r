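## Deterministic (one-way) and probabilistic sensitivity analysis.

# Run fn with a private RNG state, restoring the caller's state on exit.
with_private_rng <- function(fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

# n draws per parameter: one master seed, one deterministic L'Ecuyer-CMRG
# substream per parameter (in list order), so adding a parameter does not
# shift the draws of the others.
sample_parameter_matrix <- function(parameters, n, seed) {
  with_private_rng(function() {
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(seed)
    stream <- get(".Random.seed", envir = globalenv())
    draws <- vector("list", length(parameters))
    names(draws) <- names(parameters)
    clamped <- integer(length(parameters))
    names(clamped) <- names(parameters)
    for (i in seq_along(parameters)) {
      stream <- parallel::nextRNGStream(stream)
      assign(".Random.seed", stream, envir = globalenv())
      x <- sample_parameter(parameters[[i]], n)
      clamped[[i]] <- attr(x, "n_clamped")
      attributes(x) <- NULL
      draws[[i]] <- x
    }
    structure(draws, n_clamped = clamped)
  })
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full base-case pipeline with one parameter set to its
#' low and high input, all others held at base. Inputs are
#' `base * (1 - fraction)` and `base * (1 + fraction)`, unless the
#' parameter carries an explicit `dsa_low`/`dsa_high` range (used for
#' treatment effects whose range comes from a published interval). Inputs
#' of unit-interval parameters are clipped to \[0, 1\] with a warning.
#' The outcome metric is the incremental net monetary benefit at the
#' model's WTP.
#'
#' @param model a `cua_model`.
#' @param parameter name of the parameter to vary.
#' @param fraction relative variation (default `model$dsa_fraction`, 0.25).
#' @return One-row `data.frame`: `parameter`, `low_input`, `high_input`,
#'   `inmb_low`, `inmb_high`, `spread = |inmb_high - inmb_low|`.
#' @export
one_way_dsa <- function(model, parameter, fraction = model$dsa_fraction) {
  stopifnot(inherits(model, "cua_model"))
  spec <- model$parameters[[parameter]]
  if (is.null(spec)) stop("unknown parameter '", parameter, "'")

  if (!is.null(spec$dsa_low)) {
    lo <- spec$dsa_low; hi <- spec$dsa_high
  } else {
    lo <- spec$base * (1 - fraction)
    hi <- spec$base * (1 + fraction)
  }
  if (isTRUE(spec$unit_interval)) {
    clip_lo <- max(lo, 0); clip_hi <- min(hi, 1)
    if (clip_lo != lo || clip_hi != hi)
      warning("DSA inputs for '", parameter, "' clipped to [0, 1]", call. = FALSE)
    lo <- clip_lo; hi <- clip_hi
  }
  if (spec$family == "gamma") { lo <- max(lo, 0) }
  if (lo == hi && lo == spec$base)
    stop("empty feasible DSA range for '", parameter, "'")

  inmb_at <- function(value) {
    binding <- base_binding(model)
    binding[[parameter]] <- value
    out <- rollback(model$tree, binding)
    compare_strategies(out[[model$reference]], out[[model$intervention]],
                       model$wtp)$inmb
  }
  inmb_low <- inmb_at(lo); inmb_high <- inmb_at(hi)
  data.frame(parameter = parameter, low_input = lo, high_input = hi,
             inmb_low = inmb_low, inmb_high = inmb_high,
             spread = abs(inmb_high - inmb_low), stringsAsFactors = FALSE)
}

#' Tornado analysis
#'
#' One-way DSA over every non-fixed parameter, ordered for a tornado
#' diagram: widest INMB spread first, ties broken alphabetically by
#' parameter name.
#'
#' @inheritParams one_way_dsa
#' @return `data.frame` of [one_way_dsa()] rows sorted by decreasing
#'   `spread`, with attribute `inmb_base` (base-case INMB).
#' @export
tornado <- function(model, fraction = model$dsa_fraction) {
  vary <- names(model$parameters)[
    vapply(model$parameters, function(p) p$family != "fixed", logical(1))]
  if (!length(vary)) stop("no varying parameter for tornado analysis")
  rows <- do.call(rbind, lapply(vary, one_way_dsa, model = model, fraction = fraction))
  rows <- rows[order(-rows$spread, rows$parameter), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "inmb_base") <- base_case(model)$inmb
  rows
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' Each replication draws every non-fixed parameter once from its
#' moment-matched distribution (fixed parameters stay at base), evaluates
#' both strategies on that shared binding — so parameters common to both
#' arms induce the proper correlation — and records per-iteration costs,
#' QALYs, incremental cost and QALYs, and the incremental net monetary
#' benefit at the model's WTP. Draws use one deterministic substream per
#' parameter derived from the master `seed`, so runs are exactly
#' reproducible.
#'
#' @param model a `cua_model`.
#' @param n number of replications (default `model$n_psa`, 10,000).
#' @param seed master RNG seed (integer). Required: there is no silent
#'   default.
#' @return A `cua_psa` data frame with one row per iteration: `iteration`,
#'   one column per parameter, `cost_ref`, `qaly_ref`, `cost_int`,
#'   `qaly_int`, `delta_cost`, `delta_qaly`, `inmb`. Attributes: `wtp`,
#'   `seed`, `n`, `reference`, `intervention`, `n_clamped` (per-parameter
#'   clamp counts).
#' @export
run_psa <- function(model, n = model$n_psa, seed) {
  stopifnot(inherits(model, "cua_model"), n >= 1L)
  if (missing(seed) || is.null(seed)) stop("run_psa() requires an explicit seed")
  # surface infeasible specs before iteration 1
  for (p in model$parameters) { check_parameter_spec(p); fit_distribution(p) }

  draws <- sample_parameter_matrix(model$parameters, n, seed)
  outcomes <- rollback(model$tree, draws)
  ref <- outcomes[[model$reference]]
  int <- outcomes[[model$intervention]]
  dc <- int$cost - ref$cost
  dq <- int$qaly - ref$qaly

  res <- data.frame(iteration = seq_len(n), stringsAsFactors = FALSE)
  for (nm in names(draws)) res[[nm]] <- draws[[nm]]
  res$cost_ref <- rep_len(ref$cost, n);  res$qaly_ref <- rep_len(ref$qaly, n)
  res$cost_int <- rep_len(int$cost, n);  res$qaly_int <- rep_len(int$qaly, n)
  res$delta_cost <- rep_len(dc, n)
  res$delta_qaly <- rep_len(dq, n)
  res$inmb <- res$delta_qaly * model$wtp - res$delta_cost

  structure(res, wtp = model$wtp, seed = seed, n = n,
            reference = model$reference, intervention = model$intervention,
            n_clamped = attr(draws, "n_clamped"),
            class = c("cua_psa", "data.frame"))
}

#' Cost-effectiveness plane quadrant summary
#'
#' Proportion of PSA iterations in each quadrant of the cost-effectiveness
#' plane, keyed by the signs of the incremental QALYs and cost, plus the
#' proportion cost-effective (INMB > 0) at the run's WTP. Zero deltas are
#' counted on the favourable side — a zero incremental QALY with the
#' "more effective" half, a zero incremental cost with the "cost-saving"
#' half — so the four proportions sum to exactly 1.
#'
#' @param samples a `cua_psa` from [run_psa()].
#' @return List: `quadrants` (named numeric: `dq_pos_dc_neg`,
#'   `dq_pos_dc_pos`, `dq_neg_dc_neg`, `dq_neg_dc_pos`),
#'   `prop_cost_saving` (`delta_cost < 0`), `prop_cost_effective`
#'   (`inmb > 0`), `wtp`, `n`.
#' @export
quadrant_summary <- function(samples) {
  stopifnot(inherits(samples, "cua_psa"), nrow(samples) >= 1L)
  eff <- samples$delta_qaly >= 0   # zero counted as effective
  sav <- samples$delta_cost <= 0   # zero counted as non-costly
  quadrants <- c(
    dq_pos_dc_neg = mean(eff & sav),
    dq_pos_dc_pos = mean(eff & !sav),
    dq_neg_dc_neg = mean(!eff & sav),
    dq_neg_dc_pos = mean(!eff & !sav))
  list(quadrants = quadrants,
       prop_cost_saving = mean(samples$delta_cost < 0),
       prop_cost_effective = mean(samples$inmb > 0),
       wtp = attr(samples, "wtp"), n = nrow(samples))
}

#' Default willingness-to-pay grid
#'
#' 51 evenly spaced values from 0 to twice the model's WTP.
#'
#' @param wtp central willingness-to-pay threshold.
#' @param points number of grid points.
#' @return Numeric vector.
#' @export
default_wtp_grid <- function(wtp, points = 51L) seq(0, 2 * wtp, length.out = points)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value in the grid, the probability that the
#' intervention is cost-effective: the fraction of PSA iterations with
#' `delta_qaly * wtp - delta_cost > 0`, recomputed from the stored deltas.
#' At `wtp = 0` this equals the proportion of cost-saving iterations; as
#' `wtp` grows it tends to the proportion with positive incremental QALYs.
#'
#' @param samples a `cua_psa` from [run_psa()].
#' @param wtp_grid non-empty sorted vector of non-negative WTP values
#'   (default: [default_wtp_grid()] around the run's WTP).
#' @return `data.frame` with columns `wtp` and `probability`.
#' @export
ceac <- function(samples, wtp_grid = default_wtp_grid(attr(samples, "wtp"))) {
  stopifnot(inherits(samples, "cua_psa"))
  if (!length(wtp_grid) || any(wtp_grid < 0) || is.unsorted(wtp_grid))
    stop("wtp_grid must be non-empty, non-negative and sorted")
  prob <- vapply(wtp_grid, function(l)
    mean(samples$delta_qaly * l - samples$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @export
print.cua_psa <- function(x, ...) {
  qs <- quadrant_summary(x)
  cat(sprintf("<cua_psa> %d replications, seed %s, WTP %g (%s vs %s)\n",
              nrow(x), format(attr(x, "seed")), attr(x, "wtp"),
              attr(x, "intervention"), attr(x, "reference")))
  cat(sprintf("mean dCost %.2f, mean dQALY %.5f, mean INMB %.2f\n",
              mean(x$delta_cost), mean(x$delta_qaly), mean(x$inmb)))
  cat(sprintf("cost-saving %.1f%%, cost-effective at WTP %.1f%%\n",
              100 * qs$prop_cost_saving, 100 * qs$prop_cost_effective))
  invisible(x)
}
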