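## Synthetic patient-level cohorts and random trees: the package's own
## test bed. Cohorts carry the first-order (patient-level) structure the
## model assumes — Bernoulli repeat-RTI events, Bernoulli mortality given
## an event, gamma episode costs — so the estimation step can recover the
## model parameters and close the loop without any external data.

#' Generate a synthetic two-arm cohort
#'
#' Simulates patient-level records under the model's base-case values:
#' placebo patients experience a repeat-RTI event with probability
#' `p_repeat`, treated patients with `p_repeat * (1 - reduction)`; deaths
#' occur with probability `p_mort` given an event; event costs are drawn
#' from the gamma distribution moment-matched to (`c_rti`, its SD);
#' non-events cost 0. The drug cost (base value) is charged to every
#' patient in the treated arm. Utilities are assigned state values —
#' `u_base` for no event, `u_rti` for an event survived, 0 for death —
#' not sampled per patient: uncertainty about the state utilities is
#' second-order and belongs to the PSA.
#'
#' @param n_per_arm patients per arm (>= 1).
#' @param model a `cua_model` whose parameters include `p_repeat`,
#'   `p_mort`, `u_base`, `u_rti`, `c_rti`, `c_drug`, `reduction`
#'   (default [build_om85_model()]).
#' @param seed RNG seed.
#' @return A `cua_cohort` data frame: `arm` (`"placebo"`/`"om85"`),
#'   `repeat_event`, `death` (logical; death implies an event),
#'   `episode_cost`, `drug_cost`, `utility`. Generation parameters are
#'   attached as attribute `params`.
#' @export
generate_cohort <- function(n_per_arm, model = build_om85_model(), seed) {
  stopifnot(n_per_arm >= 1L)
  if (missing(seed) || is.null(seed)) stop("generate_cohort() requires a seed")
  b <- base_binding(model)
  needed <- c("p_repeat", "p_mort", "u_base", "u_rti", "c_rti", "c_drug", "reduction")
  missing_p <- setdiff(needed, names(b))
  if (length(missing_p))
    stop("model lacks cohort parameters: ", paste(missing_p, collapse = ", "))
  cost_fit <- fit_distribution(model$parameters[["c_rti"]])

  with_private_rng(function() {
    suppressWarnings(RNGkind("Mersenne-Twister"))
    set.seed(seed)
    n <- as.integer(n_per_arm)
    arm <- rep(c("placebo", "om85"), each = n)
    p_event <- ifelse(arm == "om85", b$p_repeat * (1 - b$reduction), b$p_repeat)
    repeat_event <- stats::runif(2L * n) < p_event
    death <- rep(FALSE, 2L * n)
    death[repeat_event] <- stats::runif(sum(repeat_event)) < b$p_mort
    episode_cost <- numeric(2L * n)
    episode_cost[repeat_event] <- stats::rgamma(
      sum(repeat_event), shape = cost_fit$params[["shape"]],
      scale = cost_fit$params[["scale"]])
    drug_cost <- ifelse(arm == "om85", b$c_drug, 0)
    utility <- ifelse(!repeat_event, b$u_base, ifelse(death, 0, b$u_rti))
    structure(
      data.frame(arm = arm, repeat_event = repeat_event, death = death,
                 episode_cost = episode_cost, drug_cost = drug_cost,
                 utility = utility, stringsAsFactors = FALSE),
      params = b, seed = seed, class = c("cua_cohort", "data.frame"))
  })
}

#' Recover model parameters from a cohort
#'
#' Estimates, with standard errors, the quantities the generator drew
#' from: per-arm event rates, the implied relative reduction
#' `1 - rate_om85 / rate_placebo` (delta-method SE), the death rate given
#' an event, and the mean and SD of the event costs (non-events excluded;
#' the SD's standard error uses the kurtosis-adjusted large-sample
#' formula). Degenerate inputs are flagged, never fatal: zero placebo
#' events leave the reduction `NA` with a flag; single-observation cells
#' leave SEs `NA`.
#'
#' @param cohort a `cua_cohort` (or any data frame with its columns).
#' @return `data.frame` with columns `parameter`, `estimate`, `se`, `flag`.
#' @export
estimate_params <- function(cohort) {
  need <- c("arm", "repeat_event", "death", "episode_cost")
  if (!all(need %in% names(cohort)))
    stop("cohort lacks columns: ", paste(setdiff(need, names(cohort)), collapse = ", "))
  if (!all(c("placebo", "om85") %in% cohort$arm))
    stop("both arms must be present")
  if (!any(cohort$repeat_event)) stop("no events in cohort; nothing to estimate")

  prop_se <- function(p, n) if (n > 1L) sqrt(p * (1 - p) / n) else NA_real_
  row <- function(parameter, estimate, se, flag = NA_character_)
    data.frame(parameter = parameter, estimate = estimate, se = se,
               flag = flag, stringsAsFactors = FALSE)

  pl <- cohort[cohort$arm == "placebo", ]
  om <- cohort[cohort$arm == "om85", ]
  p0 <- mean(pl$repeat_event); n0 <- nrow(pl)
  p1 <- mean(om$repeat_event); n1 <- nrow(om)

  if (p0 == 0) {
    red <- row("reduction", NA_real_, NA_real_,
               "reduction undefined: no placebo events")
  } else {
    r <- 1 - p1 / p0
    # delta method on the rate ratio p1/p0
    se_r <- if (p1 > 0 && n0 > 1L && n1 > 1L)
      (p1 / p0) * sqrt((1 - p1) / (p1 * n1) + (1 - p0) / (p0 * n0))
    else NA_real_
    red <- row("reduction", r, se_r,
               if (p1 == 0) "no events in om85 arm" else NA_character_)
  }

  ev <- cohort[cohort$repeat_event, ]
  pm <- mean(ev$death); ne <- nrow(ev)
  costs <- ev$episode_cost
  m <- length(costs)
  c_mean <- mean(costs)
  c_sd <- if (m > 1L) stats::sd(costs) else NA_real_
  se_mean <- if (m > 1L) c_sd / sqrt(m) else NA_real_
  se_sd <- if (m > 3L) {
    kurt <- mean((costs - c_mean)^4) / (c_sd^2 * (m - 1) / m)^2
    c_sd * sqrt(pmax(kurt - 1, 0) / (4 * m))
  } else NA_real_

  rbind(
    row("p_repeat", p0, prop_se(p0, n0)),
    row("p_event_om85", p1, prop_se(p1, n1)),
    red,
    row("p_mort", pm, prop_se(pm, ne),
        if (ne <= 1L) "too few events for SE" else NA_character_),
    row("c_rti_mean", c_mean, se_mean,
        if (m <= 1L) "single event cost" else NA_character_),
    row("c_rti_sd", c_sd, se_sd,
        if (m <= 3L) "too few event costs for SD SE" else NA_character_))
}

#' Generate a random valid decision tree
#'
#' Random trees for property testing of the rollback/path-enumeration
#' equivalence: chance nodes with 2 to `max_branching` branches, branch
#' probabilities drawn uniformly and normalized to sum to 1, subtrees
#' terminating early at random, terminal costs uniform on \[0, 1000\] and
#' utilities uniform on \[0, 1\]. `depth = 1` yields a single terminal.
#' Every generated tree passes [validate_tree()]; the same seed yields the
#' identical tree.
#'
#' @param depth maximum depth (>= 1).
#' @param max_branching maximum branches per chance node (>= 2).
#' @param seed optional RNG seed (uses current RNG state when `NULL`).
#' @return A tree node.
#' @export
random_tree <- function(depth, max_branching = 3L, seed = NULL) {
  stopifnot(depth >= 1L, max_branching >= 2L)
  gen <- function(d) {
    if (d <= 1L || stats::runif(1) < 0.3)
      return(terminal_node(cost = stats::runif(1, 0, 1000),
                           utility = stats::runif(1)))
    b <- sample(2L:max_branching, 1L)
    w <- stats::runif(b, min = 0.05)
    w <- w / sum(w)
    w[b] <- 1 - sum(w[-b])  # exact unit sum despite rounding
    chance_node(lapply(seq_len(b), function(i) chance_branch(w[i], gen(d - 1L))))
  }
  if (is.null(seed)) return(gen(depth))
  with_private_rng(function() {
    suppressWarnings(RNGkind("Mersenne-Twister"))
    set.seed(seed)
    gen(depth)
  })
}

#' Write / read a cohort as CSV
#'
#' The cohort table round-trips through a fixed-header CSV; the generation
#' parameters travel in a JSON sidecar (`<path>.meta.json`).
#'
#' @param cohort a `cua_cohort`.
#' @param path CSV file path.
#' @return `write_cohort()`: invisibly, `path`. `read_cohort()`: the
#'   `cua_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  meta <- list(params = attr(cohort, "params"), seed = attr(cohort, "seed"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$repeat_event <- as.logical(df$repeat_event)
  df$death <- as.logical(df$death)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "params") <- as.list(meta$params)
    attr(df, "seed") <- meta$seed
  }
  class(df) <- c("cua_cohort", "data.frame")
  df
}
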