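# One-way DSA / tornado and the second-order Monte Carlo PSA.

test_that("one_way_dsa evaluates the pipeline at the bracketing inputs", {
  row <- one_way_dsa(om85, "c_drug")
  expect_equal(row$low_input, 55.5)
  expect_equal(row$high_input, 92.5)
  # INMB is linear in the drug cost with slope -1: spread exactly 2*0.25*74
  expect_equal(row$spread, 37.0, tolerance = 1e-9)

  row <- one_way_dsa(om85, "c_rti")
  expect_equal(row$spread, 2 * 0.25 * 2022 * 0.13, tolerance = 1e-9)  # 131.43

  # the effect parameter uses its stored uncertainty interval, not +/-25%
  red <- one_way_dsa(om85, "reduction")
  spec <- om85$parameters$reduction
  expect_equal(red$low_input, spec$dsa_low)
  expect_equal(red$high_input, spec$dsa_high)

  expect_error(one_way_dsa(om85, "p_typo"), "unknown parameter 'p_typo'")
})

test_that("a parameter the outcome does not depend on has zero spread", {
  params <- list(parameter_spec("p", 0.2, "beta", sd = 0.05),
                 parameter_spec("c_idle", 50, "gamma", sd = 10))
  tree <- decision_node(
    a = terminal_node(cost = 10, utility = 0.9),
    b = chance_node(
      chance_branch("p", terminal_node(cost = 100, utility = 0.5)),
      chance_branch("1 - p", terminal_node(cost = 0, utility = 1))))
  m <- cua_model(params, tree, wtp = 1000)
  expect_equal(one_way_dsa(m, "c_idle")$spread, 0)
  torn <- tornado(m)
  expect_identical(torn$parameter, c("p", "c_idle"))
})

test_that("tornado sorts by spread with alphabetical tie-break and clips utilities", {
  # duplicate cost parameters produce exactly tied spreads
  params <- list(parameter_spec("z_cost", 40, "gamma", sd = 10),
                 parameter_spec("a_cost", 40, "gamma", sd = 10))
  tree <- decision_node(
    ref = terminal_node(cost = 0, utility = 0.5),
    new = terminal_node(cost = "z_cost + a_cost", utility = 0.6))
  m <- cua_model(params, tree, wtp = 1000)
  torn <- tornado(m)
  expect_identical(torn$parameter, c("a_cost", "z_cost"))
  expect_equal(torn$spread[1], torn$spread[2])

  expect_warning(one_way_dsa(om85, "u_rti"), "clipped")
  torn <- suppressWarnings(tornado(om85))
  expect_identical(torn$parameter[torn$spread == max(torn$spread)], "u_rti")
  expect_true(!is.unsorted(rev(torn$spread)))
  # base-case dominance survives every one-way scenario: INMB never flips sign
  expect_true(all(torn$inmb_low > 0) && all(torn$inmb_high > 0))
})

test_that("run_psa with all-fixed parameters reproduces the base case at n = 1", {
  params <- list(parameter_spec("p", 0.2, "fixed"),
                 parameter_spec("c", 100, "fixed"))
  tree <- decision_node(
    ref = terminal_node(cost = 0, utility = 0.9),
    new = chance_node(
      chance_branch("p", terminal_node(cost = "c", utility = 0.5)),
      chance_branch("1 - p", terminal_node(cost = 0, utility = 1))))
  m <- cua_model(params, tree, wtp = 1000)
  psa <- run_psa(m, n = 1, seed = 5)
  bc <- base_case(m)
  expect_identical(psa$delta_cost, bc$delta_cost)
  expect_identical(psa$delta_qaly, bc$delta_qaly)
  expect_identical(psa$inmb, bc$inmb)
})

test_that("run_psa is reproducible and requires a seed", {
  a <- suppressWarnings(run_psa(om85, n = 500, seed = 11))
  b <- suppressWarnings(run_psa(om85, n = 500, seed = 11))
  expect_psa_identical(a, b)
  c_ <- suppressWarnings(run_psa(om85, n = 500, seed = 12))
  expect_false(identical(a$delta_cost, c_$delta_cost))
  expect_error(run_psa(om85, n = 10), "seed")
})

test_that("PSA means of the multiplicative functionals match the base case within 3 MC SEs", {
  psa <- suppressWarnings(run_psa(om85, n = 10000, seed = 2))
  se_dc <- sd(psa$delta_cost) / sqrt(nrow(psa))
  se_dq <- sd(psa$delta_qaly) / sqrt(nrow(psa))
  expect_lt(abs(mean(psa$delta_cost) - (-188.86)), 3 * se_dc)
  expect_lt(abs(mean(psa$delta_qaly) - BASE_DQ), 3 * se_dq)
  # per-iteration INMB identity holds exactly
  expect_equal(psa$inmb, psa$delta_qaly * 5180 - psa$delta_cost, tolerance = 1e-12)
})

test_that("quadrant proportions sum to 1, respect the zero rule and feed the CEAC identities", {
  psa <- suppressWarnings(run_psa(om85, n = 2000, seed = 3))
  qs <- quadrant_summary(psa)
  expect_identical(sum(qs$quadrants), 1)
  expect_true(all(qs$quadrants >= 0))

  # one synthetic point per quadrant (with a zero-delta point counted positive-side)
  fake <- psa[1:5, ]
  fake$delta_qaly <- c(1, 1, -1, -1, 0)
  fake$delta_cost <- c(-1, 1, -1, 1, 1)
  fake$inmb <- fake$delta_qaly * attr(psa, "wtp") - fake$delta_cost
  qf <- quadrant_summary(fake)
  expect_equal(unname(qf$quadrants),  c(0.2, 0.4, 0.2, 0.2))

  # CEAC endpoints: at wtp = 0 the acceptance probability is P(dC < 0);
  # far beyond the support it is P(dQ > 0)
  curve <- ceac(psa, c(0, 5180, 1e9))
  expect_identical(curve$probability[1], mean(psa$delta_cost < 0))
  expect_identical(curve$probability[3], mean(psa$delta_qaly > 0))
  expect_identical(curve$probability[2], mean(psa$inmb > 0))
  expect_identical(ceac(psa, 5180)$probability, qs$prop_cost_effective)

  expect_error(ceac(psa, numeric(0)), "non-empty")
  expect_error(ceac(psa, c(5, 1)), "sorted")
})

test_that("the default WTP grid spans 0 to twice the threshold in 51 points", {
  g <- default_wtp_grid(5180)
  expect_length(g, 51L)
  expect_identical(range(g), c(0, 10360))
})
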