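test_that("simulation is reproducible and honours its spec", {
  spec <- sim_spec(beta = c(A = 1, B = 0.5), treatments = c("A", "B", "A+B", "placebo"),
                   inactive = "placebo", k_studies = 15, arms = c(2, 3),
                   se_range = c(0.2, 0.5), tau2 = 0.05, seed = 123)
  net1 <- simulate_network(spec)
  net2 <- simulate_network(spec)
  expect_identical(net1$contrasts, net2$contrasts)
  net3 <- simulate_network(spec, seed = 124)
  expect_false(identical(net1$contrasts, net3$contrasts))

  expect_equal(net1$k, 15L)
  expect_true(all(net1$arms %in% c(2L, 3L)))
  # two-arm standard errors stay within the requested range
  two_arm <- net1$contrasts$study %in% names(net1$arms)[net1$arms == 2L]
  expect_true(all(net1$contrasts$se[two_arm] >= 0.2 - 1e-12))
  expect_true(all(net1$contrasts$se[two_arm] <= 0.5 + 1e-12))
  # multi-arm variance structure decomposes exactly (no reconciliation warning)
  expect_no_warning(adjust_multiarm(net1))
  expect_equal(net1$truth$beta, c(A = 1, B = 0.5))
})

test_that("spec validation catches malformed truths", {
  expect_error(sim_spec(beta = c(A = 1), treatments = c("A", "B")),
               class = "cnma_validation_error")
  expect_error(sim_spec(beta = c(A = 1, B = 1), treatments = c("A", "B"),
                        interactions = c("A*B" = 0.5)),
               class = "cnma_validation_error")  # A+B occurs in no treatment
  expect_error(sim_spec(beta = c(A = 1), treatments = c("A", "P"),
                        inactive = "P", se_range = c(0, 1)))
})

test_that("heterogeneity is generated at the stated between-study variance", {
  # with many studies the moment estimator should land near tau2_true
  spec <- sim_spec(beta = c(A = 0.5, B = 0.2, C = 0),
                   treatments = tab1_treatments, inactive = "placebo",
                   k_studies = 400, se_range = c(0.15, 0.3), tau2 = 0.08,
                   seed = 31)
  net <- simulate_network(spec)
  fit <- fit_cnma(net, build_combination(net, inactive = "placebo"),
                  effects = "random")
  expect_equal(fit$tau2, 0.08, tolerance = 0.35)
})

test_that("cli fit agrees exactly with the library path and writes a bundle", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "net.csv")
  utils::write.csv(tab1_data(d = c(1, 2, 0, 1, 1, 1)), f, row.names = FALSE)

  code <- cli_main(c("fit", "--input", f, "--model", "standard",
                     "--outdir", dir)) |> suppressMessages()
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "results.json")))
  expect_true(file.exists(file.path(dir, "league.csv")))
  expect_true(file.exists(file.path(dir, "forest.txt")))

  league <- utils::read.csv(file.path(dir, "league.csv"))
  fit <- fit_nma(read_contrasts(f))
  expected <- league_table(fit, exponentiate = TRUE)
  expect_equal(league$estimate, expected$estimate)   # bit-exact via CSV round trip

  code2 <- cli_main(c("fit", "--input", f, "--model", "additive",
                      "--inactive", "placebo", "--effects", "random",
                      "--outdir", file.path(dir, "add"))) |> suppressMessages()
  expect_equal(code2, 0L)
  bundle <- jsonlite::read_json(file.path(dir, "add", "results.json"),
                                simplifyVector = TRUE)
  expect_equal(bundle$model, "additive")
  expect_equal(sort(bundle$estimates$components$term), c("A", "B", "C"))
})

test_that("cli surfaces validation problems as exit code 2", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines("study,treat1,treat2,TE", bad)   # seTE missing
  expect_equal(suppressMessages(cli_main(c("fit", "--input", bad))), 2L)
  expect_equal(suppressMessages(cli_main(c("fit"))), 2L)
  expect_equal(suppressMessages(cli_main(c("nonsense"))), 2L)
  f <- file.path(dir, "net.csv")
  utils::write.csv(tab1_data(), f, row.names = FALSE)
  expect_equal(suppressMessages(
    cli_main(c("fit", "--input", f, "--model", "interaction"))), 2L)
})

test_that("cli simulate and compare round-trip through files", {
  dir <- withr::local_tempdir()
  sim <- file.path(dir, "sim.csv")
  code <- suppressMessages(cli_main(c(
    "simulate", "--components", "A=1,B=0.5", "--treatments", "A,B,A+B,placebo",
    "--k", "25", "--tau2", "0.02", "--seed", "7",
    "--inactive", "placebo", "--out", sim)))
  expect_equal(code, 0L)
  net <- read_contrasts(sim)
  expect_equal(net$k, 25L)

  out <- utils::capture.output(code2 <- suppressMessages(cli_main(c(
    "compare", "--input", sim, "--inactive", "placebo",
    "--interactions", "A*B", "--outdir", dir))))
  expect_equal(code2, 0L)
  tab <- utils::read.csv(file.path(dir, "model_comparison.csv"))
  expect_setequal(tab$model,
                  c("standard", "interaction", "additive",
                    "additive vs standard", "interaction vs standard",
                    "additive vs interaction"))
  qd <- function(m) tab$Q[tab$model == m]
  expect_equal(qd("additive vs interaction") + qd("interaction vs standard"),
               qd("additive vs standard"), tolerance = 1e-8)
})
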