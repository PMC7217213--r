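test_that("single placebo-controlled study identifies its component exactly", {
  net <- nma_network(tibble::tibble(
    study = "s1", treat1 = "A", treat2 = "placebo", effect = 0.5, se = 1))
  fit <- fit_cnma(net, build_combination(net, inactive = "placebo"))
  expect_equal(unname(fit$beta_hat["A"]), 0.5)
  expect_equal(unname(diag(fit$cov_beta)), 1)
})

test_that("hypothetical network matches the dense normal-equations oracle", {
  net <- tab1_network(d = c(1, 2, 0, 1, 1, 1))
  cs <- build_combination(net, inactive = "placebo")
  fit <- fit_cnma(net, cs)
  Xa <- cnma:::build_design(net, cs)
  or <- oracle_wls(Xa, rep(1, 6), net$contrasts$effect)
  expect_equal(unname(fit$beta_hat), or$beta, tolerance = 1e-10)
  expect_equal(unname(fit$theta_hat),
               unname(drop(cs$C[net$treatments, ] %*% fit$beta_hat)))
  expect_equal(unname(fit$delta_hat), unname(drop(Xa %*% fit$beta_hat)))
})

test_that("a saturated component structure reproduces the standard model", {
  net <- nma_network(tibble::tibble(
    study = c("s1", "s2", "s3", "s4"), treat1 = c("A", "B", "A", "A"),
    treat2 = c("B", "C", "C", "P"), effect = c(1, 1, 1, 0.5),
    se = c(1, 0.8, 1.2, 1)))
  cs <- build_combination(net, inactive = "P")  # active treatments = components
  std <- fit_nma(net)
  cn <- fit_cnma(net, cs)
  expect_equal(cn$Q, std$Q, tolerance = 1e-10)
  expect_equal(unname(cn$delta_hat), unname(std$delta_hat), tolerance = 1e-10)
  cmp <- additivity_test(std, cn)
  expect_equal(cmp$Q_diff, 0, tolerance = 1e-10)
  expect_equal(cmp$df, 0L)
})

test_that("exactly additive data give Q_a = 0 and exact recovery", {
  net <- tab1_network(d = c(-0.5, -0.7, 0.8, -0.2, -1, 1), se = 1)
  # d above is Xa %*% beta for beta = (1, 0.5, 0.2)
  cs <- build_combination(net, inactive = "placebo")
  fit <- fit_cnma(net, cs)
  expect_equal(unname(fit$beta_hat), c(1, 0.5, 0.2), tolerance = 1e-10)
  expect_equal(fit$Q, 0, tolerance = 1e-12)
})

test_that("noiseless simulations recover the component truth", {
  spec <- sim_spec(beta = c(A = 1, B = 0.5, C = -0.2),
                   treatments = tab1_treatments, inactive = "placebo",
                   k_studies = 12, se_range = c(1e-6, 2e-6), seed = 99)
  net <- simulate_network(spec)
  fit <- fit_cnma(net, build_combination(net, inactive = "placebo"))
  expect_equal(unname(fit$beta_hat), c(1, 0.5, -0.2), tolerance = 1e-6)
})

test_that("never-informative and non-identified components raise errors", {
  # C appears on both sides of the only comparison -> all-zero Xa column
  net <- nma_network(tibble::tibble(
    study = "s1", treat1 = "A+C", treat2 = "B+C", effect = 0.3, se = 1))
  cs <- build_combination(net)
  expect_error(fit_cnma(net, cs), class = "cnma_identification_error")
  # opt-in keeps the estimable part usable
  fit <- fit_cnma(net, cs, allow_deficient = TRUE)
  expect_true(estimable(fit, c(A = 1, B = -1)))
  expect_false(estimable(fit, c(A = 1)))
  expect_error(component_contrast(fit, c(C = 1)),
               class = "cnma_estimability_error")
})

test_that("projection commutativity, Pythagoras and Ha delta_nma identities", {
  withr::local_seed(31)
  for (i in 1:25) {
    rc <- random_component_network()
    std <- fit_nma(rc$network)
    cn <- fit_cnma(rc$network, rc$comps)
    H <- std$H; Ha <- cn$Ha
    expect_lt(max(abs(Ha %*% H - Ha)), 1e-10)
    expect_lt(max(abs(H %*% Ha - Ha)), 1e-10)
    expect_lt(max(abs(Ha %*% Ha - Ha)), 1e-10)
    # delta_a = Ha d = Ha delta_nma
    expect_equal(unname(cn$delta_hat),
                 unname(drop(Ha %*% std$delta_hat)), tolerance = 1e-10)
    # Pythagoras: Qa = Q + (delta_a - delta_nma)' W (delta_a - delta_nma)
    w <- std$weights_common
    gap <- sum(w * (cn$delta_hat - std$delta_hat)^2)
    expect_equal(cn$Q, std$Q + gap, tolerance = 1e-8)
    expect_gte(cn$Q, std$Q - 1e-12)
    # dense oracle agreement for the component fit
    or <- oracle_wls(cn$X, w, rc$network$contrasts$effect)
    expect_equal(unname(cn$beta_hat), or$beta, tolerance = 1e-8)
    expect_equal(unname(cn$cov_beta), or$cov_beta, tolerance = 1e-8)
  }
})

test_that("q_cnma reports n_a - k - r degrees of freedom", {
  net <- tab1_network()
  cs <- build_combination(net, inactive = "placebo")
  fit <- fit_cnma(net, cs)
  qa <- q_cnma(net, fit)
  expect_equal(qa$df, net$n_a - net$k - fit$rank)
  expect_equal(qa$df, net$k - fit$rank)  # two-arm-only network
  expect_equal(qa$Q, fit$Q, tolerance = 1e-12)
})

test_that("additivity test decomposes Q and checks its preconditions", {
  net <- tab1_network(d = c(1, 2, 0, 1, 1, 1))
  cs <- build_combination(net, inactive = "placebo")
  std <- fit_nma(net)
  cn <- fit_cnma(net, cs)
  cmp <- additivity_test(std, cn)
  expect_equal(cmp$Q_diff, cn$Q - std$Q, tolerance = 1e-10)
  expect_equal(cmp$df, net$n - cn$rank - 1L)
  expect_lt(cmp$pythagoras_gap, 1e-10)

  other <- tab1_network(d = c(0, 0, 0, 0, 0, 0))
  expect_error(additivity_test(fit_nma(other), cn),
               class = "cnma_usage_error")
})

test_that("nested model comparisons telescope across the model hierarchy", {
  withr::local_seed(41)
  # hypothetical topology extended with a C-vs-placebo study so that both
  # A*B and B*C interaction columns are identifiable
  net <- nma_network(tibble::tibble(
    study = paste0("Study ", 1:7),
    treat1 = c("A", "A", "A+B", "A+B", "B+C", "A", "C"),
    treat2 = c("A+B", "A+B+C", "B+C", "A+B+C", "A+B+C", "placebo", "placebo"),
    effect = stats::rnorm(7), se = stats::runif(7, 0.5, 1)))
  cs <- build_combination(net, inactive = "placebo")
  std <- fit_nma(net)
  addf <- fit_cnma(net, cs)
  intf <- fit_cnma(net, add_interactions(cs, "A*B"))

  self_cmp <- compare_nested(addf, addf)
  expect_equal(self_cmp$Q_diff, 0, tolerance = 1e-10)
  expect_equal(self_cmp$df, 0L)

  t_add_int <- compare_nested(intf, addf)
  t_add_std <- additivity_test(std, addf)
  t_int_std <- additivity_test(std, intf)
  expect_equal(t_add_int$df, 1L)
  expect_equal(t_add_int$Q_diff + t_int_std$Q_diff, t_add_std$Q_diff,
               tolerance = 1e-8)
  expect_gte(t_add_int$Q_diff, 0)

  # non-nested designs are refused: additive-with-A*B vs additive-with-B*C
  # (neither span contains the other)
  intf2 <- fit_cnma(net, add_interactions(cs, "B*C"))
  expect_error(compare_nested(intf, intf2), class = "cnma_usage_error")
})

test_that("interaction model captures a true synergy the additive model misses", {
  spec <- sim_spec(beta = c(A = 0.6, B = 0.3, C = 0.1),
                   treatments = tab1_treatments, inactive = "placebo",
                   interactions = c("A*B" = 0.8),
                   k_studies = 30, se_range = c(0.05, 0.1), seed = 7)
  net <- simulate_network(spec)
  cs <- build_combination(net, inactive = "placebo")
  addf <- fit_cnma(net, cs)
  intf <- fit_cnma(net, add_interactions(cs, "A*B"))
  expect_equal(unname(intf$beta_hat["A*B"]), 0.8, tolerance = 0.15)
  expect_lt(intf$Q, addf$Q)
  expect_lt(compare_nested(intf, addf)$p, 0.01)
})

test_that("combination OR is the product of component ORs", {
  net <- tab1_network(d = c(1, 2, 0, 1, 1, 1))
  cs <- build_combination(net, inactive = "placebo")
  fit <- fit_cnma(net, cs)
  expect_equal(exp(fit$theta_hat[["A+B"]]),
               exp(fit$beta_hat[["A"]]) * exp(fit$beta_hat[["B"]]),
               tolerance = 1e-12)
})

test_that("random-effects CNMA re-estimates tau2 under its own design", {
  withr::local_seed(53)
  spec <- sim_spec(beta = c(A = 1, B = 0.5, C = -0.2),
                   treatments = tab1_treatments, inactive = "placebo",
                   k_studies = 40, tau2 = 0.1, seed = 17)
  net <- simulate_network(spec)
  cs <- build_combination(net, inactive = "placebo")
  std <- fit_nma(net, effects = "random")
  cn <- fit_cnma(net, cs, effects = "random")
  expect_gt(cn$tau2, 0)
  expect_false(isTRUE(all.equal(cn$tau2, std$tau2)))  # per-design estimates
  # random-effects CIs are wider than common-effect ones
  expect_true(all(sqrt(diag(cn$cov_beta)) >=
                    sqrt(diag(fit_cnma(net, cs)$cov_beta)) - 1e-12))
})
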