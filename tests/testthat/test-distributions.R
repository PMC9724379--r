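# Moment matching and parameter sampling.

test_that("beta moment matching reproduces the closed form and rejects infeasible moments", {
  expect_equal(beta_from_moments(0.20, 0.05), c(alpha = 12.6, beta = 50.4),
               tolerance = 1e-12)
  expect_equal(beta_from_moments(0.94, 0.01), c(alpha = 529.22, beta = 33.78),
               tolerance = 1e-10)
  expect_error(beta_from_moments(0.5, 0.5), "infeasible moments")
  expect_error(beta_from_moments(1.2, 0.1), "0 < mean < 1")
  expect_error(parameter_spec("p", 0.5, "beta", sd = 0.5), "infeasible moments.*'p'")
})

test_that("gamma moment matching reproduces the closed form", {
  expect_equal(gamma_from_moments(74, 18.5), c(shape = 16, scale = 4.625),
               tolerance = 1e-12)
  fit <- gamma_from_moments(2022, 505)
  expect_equal(unname(fit["shape"]), 2022^2 / 505^2, tolerance = 1e-12)
  expect_equal(unname(fit["scale"]), 505^2 / 2022, tolerance = 1e-12)
  # CV = 1 is exponential for any mean
  for (m in c(0.5, 7, 300)) {
    expect_equal(unname(gamma_from_moments(m, m)["shape"]), 1, tolerance = 1e-12)
  }
  expect_error(gamma_from_moments(-1, 1), "mean > 0")
})

test_that("lognormal moment matching reproduces the closed form", {
  fit <- lognormal_from_moments(0.65, 0.07)
  expect_identical(round(unname(fit["meanlog"]), 5), -0.43655)
  expect_identical(round(unname(fit["sdlog"]), 5), 0.10738)
  expect_equal(unname(lognormal_from_moments(2, 2)["sdlog"]^2), log(2),
               tolerance = 1e-12)
  # degenerate limit: sd -> 0 gives meanlog -> log(mean) -> 0 at mean 1
  tiny <- lognormal_from_moments(1, 1e-9)
  expect_equal(unname(tiny["meanlog"]), 0, tolerance = 1e-12)
  expect_lt(unname(tiny["sdlog"]), 1e-8)
  expect_error(lognormal_from_moments(1, 0), "sd > 0")
})

test_that("round trip moments -> parameters -> analytic moments is exact for all families", {
  cases <- list(
    parameter_spec("a", 0.20, "beta", sd = 0.05),
    parameter_spec("b", 0.87, "beta", sd = 0.2),
    parameter_spec("c", 2022, "gamma", sd = 505),
    parameter_spec("d", 74, "gamma", sd = 18.5),
    parameter_spec("e", 0.65, "lognormal", sd = 0.07),
    parameter_spec("f", 5180, "fixed"))
  for (spec in cases) {
    mom <- analytic_moments(spec)
    expect_equal(unname(mom["mean"]), spec$base, tolerance = 1e-12)
    expect_equal(unname(mom["sd"]), spec$sd %||% 0, tolerance = 1e-12)
  }
})

test_that("every worked-model parameter row passes the feasibility screen", {
  # in particular u_rti: 0.2^2 = 0.04 < 0.87 * 0.13 = 0.1131
  expect_silent(lapply(om85$parameters, check_parameter_spec))
  expect_length(om85$parameters, 7L)
})

test_that("sampling is deterministic, clamped and fixed-aware", {
  fixed <- parameter_spec("wtp", 5180, "fixed")
  expect_identical(sample_parameter(fixed, 5)[1:5], rep(5180, 5))

  spec <- parameter_spec("c", 2022, "gamma", sd = 505)
  set.seed(99); a <- sample_parameter(spec, 1000)
  set.seed(99); b <- sample_parameter(spec, 1000)
  expect_identical(a, b)

  # forced clamping: lognormal marked unit-interval with heavy spread
  wild <- parameter_spec("r", 0.9, "lognormal", sd = 0.8, unit_interval = TRUE)
  set.seed(1)
  expect_warning(x <- sample_parameter(wild, 500), "clamped")
  expect_true(all(x >= 0 & x <= 1))
  expect_gt(attr(x, "n_clamped"), 0L)
})

test_that("sampled moments match requested moments (draw-level check)", {
  n <- 2e5
  cases <- list(
    list(parameter_spec("u", 0.87, "beta", sd = 0.2), 0.87, 0.2),
    list(parameter_spec("c", 2022, "gamma", sd = 505), 2022, 505),
    list(parameter_spec("r", 0.65, "lognormal", sd = 0.07,
                        unit_interval = FALSE), 0.65, 0.07))
  set.seed(2024)
  for (case in cases) {
    x <- sample_parameter(case[[1]], n)
    expect_equal(mean(x), case[[2]], tolerance = 0.01)
    expect_equal(sd(x), case[[3]], tolerance = 0.02)
  }
})

test_that("clamp frequency of the treatment-effect lognormal matches its tail mass", {
  # P(draw > 1) = 1 - plnorm(1, meanlog, sdlog): the exact tail oracle
  fit <- lognormal_from_moments(0.65, 0.07)
  p_tail <- stats::plnorm(1, fit["meanlog"], fit["sdlog"], lower.tail = FALSE)
  n <- 1e6
  spec <- parameter_spec("red", 0.65, "lognormal", sd = 0.07, unit_interval = TRUE)
  set.seed(7)
  x <- suppressWarnings(sample_parameter(spec, n))
  k <- attr(x, "n_clamped")
  lam <- n * p_tail   # ~24 expected: rare but not absent
  expect_gt(lam, 5)
  expect_true(k >= qpois(1e-5, lam) && k <= qpois(1 - 1e-5, lam))
})
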