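# Configuration reading/writing and the command-line front end.

shipped_config <- function() system.file("extdata", "om85.json", package = "cuatree")

write_json_config <- function(cfg) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}

minimal_config <- function() {
  list(schema_version = 1,
       parameters = list(
         list(name = "p", base = 0.2, family = "beta", sd = 0.05),
         list(name = "c", base = 100, family = "gamma", sd = 25)),
       tree = list(kind = "decision", strategies = list(
         ref = list(kind = "terminal", cost = 0, utility = 0.9),
         new = list(kind = "chance", branches = list(
           list(probability = "p",
                node = list(kind = "terminal", cost = "c", utility = 0.5)),
           list(probability = "1 - p",
                node = list(kind = "terminal", cost = 0, utility = 1)))))),
       analysis = list(wtp = 1000, n_psa = 100))
}

test_that("the shipped configuration loads and round-trips the model inputs exactly", {
  model <- read_config(shipped_config())
  expect_s3_class(model, "cua_model")
  built <- build_om85_model()
  for (nm in names(built$parameters)) {
    expect_true(model$parameters[[nm]]$base == built$parameters[[nm]]$base)
    expect_true((model$parameters[[nm]]$sd %||% 0) == (built$parameters[[nm]]$sd %||% 0))
    expect_identical(model$parameters[[nm]]$family, built$parameters[[nm]]$family)
  }
  expect_true(model$wtp == 5180)
  bc <- base_case(model)
  expect_equal(bc$cost_reference, 404.40, tolerance = 1e-12)
  expect_equal(bc$qaly_intervention, 0.9346128, tolerance = 1e-12)
  expect_match(attr(model, "config_md5"), "^[0-9a-f]{32}$")
})

test_that("write_config/read_config round-trips an arbitrary model", {
  path <- tempfile(fileext = ".json")
  write_config(build_om85_model(), path)
  model <- read_config(path)
  expect_equal(base_case(model)$inmb, base_case(build_om85_model())$inmb,
               tolerance = 1e-12)
  expect_identical(model$reference, "placebo")
})

test_that("invalid configurations fail with all errors listed, named precisely", {
  cfg <- minimal_config()
  cfg$tree$strategies$new$branches[[1]]$probability <- "p_typo"
  expect_error(read_config(write_json_config(cfg)), "'p_typo'")

  cfg <- minimal_config()
  cfg$tree$strategies$new$branches[[1]]$probability <- 0.2
  cfg$tree$strategies$new$branches[[2]]$probability <- 0.7
  expect_error(read_config(write_json_config(cfg)), "sum to 0.9")

  # several independent defects reported together
  cfg <- minimal_config()
  cfg$bogus <- 1
  cfg$schema_version <- 99
  cfg$parameters[[1]]$family <- "beta"
  cfg$parameters[[1]]$sd <- 0.9                   # infeasible moments
  cfg$tree$strategies$ref$kind <- "teminal"       # unknown kind
  err <- tryCatch(read_config(write_json_config(cfg)), error = conditionMessage)
  expect_match(err, "unknown top-level key")
  expect_match(err, "schema_version 99")
  expect_match(err, "infeasible moments")
  expect_match(err, "unknown node kind 'teminal'")

  expect_error(read_config(tempfile()), "not found")
})

test_that("the CLI dispatches, writes outputs and reports proper exit codes", {
  out <- withr::local_tempdir()
  expect_identical(cua_cli(c("validate", shipped_config())), 0L)

  expect_identical(cua_cli(c("base-case", shipped_config(), "--out", out)), 0L)
  tab <- read.csv(file.path(out, "base_case.csv"))
  expect_identical(tab$cost, c(404.40, 215.54))
  meta <- jsonlite::read_json(file.path(out, "run_metadata.json"))
  expect_identical(meta$command, "base-case")
  expect_match(meta$config_md5, "^[0-9a-f]{32}$")

  # utility DSA inputs at +25% exceed 1 and are clipped, with a warning
  expect_identical(suppressWarnings(cua_cli(c("dsa", shipped_config(), "--out", out))), 0L)
  torn <- read.csv(file.path(out, "tornado.csv"))
  expect_identical(nrow(torn), 7L)
})

test_that("CLI PSA runs are reproducible file-for-file and round-trip their tables", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  expect_identical(
    cua_cli(c("psa", shipped_config(), "--n", "400", "--seed", "42", "--out", out1)), 0L)
  expect_identical(
    cua_cli(c("psa", shipped_config(), "--n", "400", "--seed", "42", "--out", out2)), 0L)
  expect_identical(readLines(file.path(out1, "psa_draws.csv")),
                   readLines(file.path(out2, "psa_draws.csv")))
  draws <- read.csv(file.path(out1, "psa_draws.csv"))
  expect_identical(nrow(draws), 400L)
  expect_equal(draws$inmb, draws$delta_qaly * 5180 - draws$delta_cost,
               tolerance = 1e-9)

  expect_identical(
    cua_cli(c("ceac", shipped_config(), "--n", "200", "--seed", "1", "--out", out1)), 0L)
  curve <- read.csv(file.path(out1, "ceac.csv"))
  expect_identical(nrow(curve), 51L)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))

  expect_identical(
    cua_cli(c("simulate-cohort", shipped_config(), "--n", "50", "--seed", "3",
              "--out", out1)), 0L)
  expect_identical(nrow(read_cohort(file.path(out1, "cohort.csv"))), 100L)
})

test_that("CLI usage errors exit nonzero with a message", {
  broken <- write_json_config({
    cfg <- minimal_config()
    cfg$tree$strategies$new$branches[[1]]$probability <- "p_typo"
    cfg
  })
  expect_message(st <- cua_cli(c("validate", broken)), "p_typo")
  expect_identical(st, 1L)
  expect_message(st <- cua_cli(c("frobnicate", "x.json")), "unknown subcommand")
  expect_identical(st, 2L)
  expect_message(st <- cua_cli(c("base-case", shipped_config(), "--bad", "1")),
                 "unknown flag")
  expect_identical(st, 2L)
  expect_message(st <- cua_cli(character(0)), "usage")
  expect_identical(st, 2L)
  expect_message(st <- cua_cli(c("base-case")), "needs a configuration")
  expect_identical(st, 2L)
})
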