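# Shared fixtures, all built in code.

om85 <- build_om85_model()

# Hand path enumeration of the worked model at Table-of-inputs base values:
# placebo: 0.2*2022 = 404.40; 0.8*0.94 + 0.2*(0.992*0.87 + 0.008*0) = 0.924608
# om85:    74 + 0.07*2022 = 215.54; 0.93*0.94 + 0.07*0.992*0.87 = 0.9346128
BASE_PLACEBO <- list(cost = 404.40, qaly = 0.924608)
BASE_OM85    <- list(cost = 215.54, qaly = 0.9346128)
BASE_DQ      <- 0.13 * (0.94 - 0.992 * 0.87)   # 0.0100048

# Two-branch chance tree with literal probabilities.
simple_chance_tree <- function(p = 0.2) {
  chance_node(
    chance_branch(p, terminal_node(cost = 500, utility = 0.7)),
    chance_branch(1 - p, terminal_node(cost = 0, utility = 0.95)))
}

# Weighted aggregation of the path-enumeration oracle, per strategy.
paths_expectation <- function(paths) {
  out <- lapply(split(paths, paths$strategy), function(d)
    list(cost = sum(d$probability * d$cost),
         qaly = sum(d$probability * d$utility)))
  out[unique(paths$strategy)]
}

expect_psa_identical <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}
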