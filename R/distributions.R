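#' Parameter specifications and moment-matched distributions
#'
#' Uncertain model inputs are described by their mean and standard
#' deviation plus a distribution family, the way health-technology
#' assessment tables usually print them: beta for probabilities and
#' utilities, gamma for costs, lognormal for relative treatment effects,
#' or `fixed` for quantities held constant. The family's shape parameters
#' are recovered from (mean, SD) by the method of moments, so the fitted
#' distribution has exactly the requested first two moments.
#'
#' @param name parameter identifier (must be a valid R name; it is how the
#'   tree refers to the parameter).
#' @param base base-case value (the mean of the fitted distribution).
#' @param family one of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param sd standard deviation (0 or omitted for `fixed`).
#' @param dsa_low,dsa_high optional explicit one-way sensitivity range
#'   bracketing `base`; when absent, deterministic sensitivity analysis
#'   uses `base * (1 +/- fraction)`.
#' @param unit_interval logical: must draws lie in \[0, 1\]? Defaults to
#'   `TRUE` for the beta family. Out-of-range draws from other families
#'   (e.g. a lognormal risk reduction) are clamped, and the clamp count is
#'   attached to the draw vector.
#' @param label optional human-readable description.
#' @return A `cua_parameter` object.
#' @examples
#' parameter_spec("p_repeat", 0.20, "beta", sd = 0.05)
#' parameter_spec("c_rti", 2022, "gamma", sd = 505)
#' @export
parameter_spec <- function(name, base, family = c("fixed", "beta", "gamma", "lognormal"),
                           sd = 0, dsa_low = NULL, dsa_high = NULL,
                           unit_interval = NULL, label = NULL) {
  family <- match.arg(family)
  if (!is.character(name) || length(name) != 1L || name != make.names(name))
    stop("parameter name must be a single valid identifier")
  if (is.null(unit_interval)) unit_interval <- family == "beta"
  spec <- structure(
    list(name = name, base = base, family = family, sd = sd,
         dsa_low = dsa_low, dsa_high = dsa_high,
         unit_interval = unit_interval, label = label),
    class = "cua_parameter")
  check_parameter_spec(spec)
  spec
}

check_parameter_spec <- function(spec) {
  nm <- spec$name
  if (!is.numeric(spec$base) || length(spec$base) != 1L || !is.finite(spec$base))
    stop("parameter '", nm, "': base value must be a finite number")
  switch(spec$family,
    fixed = {
      if (!is.null(spec$sd) && length(spec$sd) && spec$sd != 0)
        stop("parameter '", nm, "': fixed family requires sd absent or 0")
    },
    beta = {
      if (spec$base <= 0 || spec$base >= 1)
        stop("parameter '", nm, "': beta family requires 0 < base < 1")
      if (spec$sd <= 0) stop("parameter '", nm, "': beta family requires sd > 0")
      if (spec$sd^2 >= spec$base * (1 - spec$base))
        stop("infeasible moments for parameter '", nm,
             "': sd^2 must be < mean * (1 - mean)")
    },
    gamma = ,
    lognormal = {
      if (spec$base <= 0) stop("parameter '", nm, "': ", spec$family,
                               " family requires base > 0")
      if (spec$sd <= 0) stop("parameter '", nm, "': ", spec$family,
                             " family requires sd > 0")
    })
  if (!is.null(spec$dsa_low) && !is.null(spec$dsa_high)) {
    if (spec$dsa_low > spec$base || spec$dsa_high < spec$base)
      stop("parameter '", nm, "': DSA range [", spec$dsa_low, ", ",
           spec$dsa_high, "] must bracket the base value ", spec$base)
  } else if (xor(is.null(spec$dsa_low), is.null(spec$dsa_high))) {
    stop("parameter '", nm, "': dsa_low and dsa_high must be given together")
  }
  invisible(spec)
}

#' Moment-matching parameterizations
#'
#' Closed-form method-of-moments inversions. Each returns shape parameters
#' such that the distribution's analytic mean and SD equal the inputs
#' exactly:
#' \describe{
#'   \item{beta}{`alpha = m * nu`, `beta = (1 - m) * nu` with
#'     `nu = m (1 - m) / s^2 - 1`; requires `s^2 < m (1 - m)`.}
#'   \item{gamma}{`shape = (m / s)^2`, `scale = s^2 / m`.}
#'   \item{lognormal}{`sdlog^2 = log(1 + (s / m)^2)`,
#'     `meanlog = log(m) - sdlog^2 / 2` (natural-scale moments).}
#' }
#'
#' @param mean,sd requested natural-scale mean and standard deviation.
#' @return Named numeric vector of shape parameters: `c(alpha, beta)`,
#'   `c(shape, scale)` or `c(meanlog, sdlog)`.
#' @examples
#' beta_from_moments(0.20, 0.05)   # alpha 12.6, beta 50.4
#' gamma_from_moments(74, 18.5)    # shape 16, scale 4.625
#' lognormal_from_moments(0.65, 0.07)
#' @name moment-matching
NULL

#' @rdname moment-matching
#' @export
beta_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta moments require 0 < mean < 1")
  if (sd <= 0) stop("beta moments require sd > 0")
  if (sd^2 >= mean * (1 - mean))
    stop("infeasible moments: sd^2 must be < mean * (1 - mean)")
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' @rdname moment-matching
#' @export
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma moments require mean > 0 and sd > 0")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' @rdname moment-matching
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("lognormal moments require mean > 0 and sd > 0")
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Fit the sampling distribution of a parameter
#'
#' @param spec a [parameter_spec()].
#' @return List with `family` and the moment-matched shape `params`
#'   (empty for `fixed`).
#' @export
fit_distribution <- function(spec) {
  stopifnot(inherits(spec, "cua_parameter"))
  params <- switch(spec$family,
    fixed     = numeric(),
    beta      = beta_from_moments(spec$base, spec$sd),
    gamma     = gamma_from_moments(spec$base, spec$sd),
    lognormal = lognormal_from_moments(spec$base, spec$sd))
  list(family = spec$family, params = params)
}

#' Draw from a parameter's fitted distribution
#'
#' Uses the current RNG state (seed control belongs to the caller; the PSA
#' driver assigns one deterministic substream per parameter). Draws of
#' unit-interval parameters are clamped to \[0, 1\]; the number of clamped
#' draws is attached as attribute `n_clamped` and reported by a warning
#' when positive. A `fixed` parameter returns its base value and consumes
#' no random numbers.
#'
#' @param spec a [parameter_spec()].
#' @param n number of draws.
#' @return Numeric vector of length `n` with attribute `n_clamped`.
#' @export
sample_parameter <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "cua_parameter"), n >= 1L)
  fit <- fit_distribution(spec)
  x <- switch(fit$family,
    fixed     = rep(spec$base, n),
    beta      = stats::rbeta(n, fit$params[["alpha"]], fit$params[["beta"]]),
    gamma     = stats::rgamma(n, shape = fit$params[["shape"]],
                              scale = fit$params[["scale"]]),
    lognormal = stats::rlnorm(n, fit$params[["meanlog"]], fit$params[["sdlog"]]))
  n_clamped <- 0L
  if (isTRUE(spec$unit_interval)) {
    out_of_range <- x < 0 | x > 1
    n_clamped <- sum(out_of_range)
    if (n_clamped > 0L) {
      x <- pmin(pmax(x, 0), 1)
      warning(n_clamped, " draw(s) of parameter '", spec$name,
              "' clamped to [0, 1]", call. = FALSE)
    }
  }
  attr(x, "n_clamped") <- n_clamped
  x
}

# Analytic mean/sd implied by a fitted spec (round-trip check helper).
analytic_moments <- function(spec) {
  fit <- fit_distribution(spec)
  switch(fit$family,
    fixed = c(mean = spec$base, sd = 0),
    beta = {
      a <- fit$params[["alpha"]]; b <- fit$params[["beta"]]
      c(mean = a / (a + b), sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = {
      k <- fit$params[["shape"]]; s <- fit$params[["scale"]]
      c(mean = k * s, sd = sqrt(k) * s)
    },
    lognormal = {
      mu <- fit$params[["meanlog"]]; sg <- fit$params[["sdlog"]]
      m <- exp(mu + sg^2 / 2)
      c(mean = m, sd = m * sqrt(exp(sg^2) - 1))
    })
}

#' @export
print.cua_parameter <- function(x, ...) {
  rng <- if (!is.null(x$dsa_low)) sprintf(", DSA [%g, %g]", x$dsa_low, x$dsa_high) else ""
  cat(sprintf("<parameter %s> base %g, %s%s%s\n", x$name, x$base, x$family,
              if (x$family == "fixed") "" else sprintf(" (SD %g)", x$sd), rng))
  invisible(x)
}
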