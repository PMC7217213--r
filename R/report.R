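#' League table of all pairwise treatment comparisons
#'
#' Every ordered treatment pair with its network estimate and Wald
#' confidence interval, derived from the fitted treatment effects and their
#' full covariance (for the standard model the Laplacian pseudoinverse, for
#' component models `C (Xa' W Xa)^+ C'`).
#'
#' @param fit an `nma_fit` or `cnma_fit`.
#' @param exponentiate report odds/risk ratios instead of additive effects.
#' @param conf.level confidence level.
#' @return tibble with `treat1`, `treat2`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (effect of `treat1` vs `treat2`).
#' @export
league_table <- function(fit, exponentiate = FALSE, conf.level = 0.95) {
  stopifnot(inherits(fit, c("nma_fit", "cnma_fit")))
  theta <- fit$theta_hat
  V <- fit$cov_theta
  trts <- names(theta)
  pairs <- utils::combn(trts, 2L)
  est <- theta[pairs[1L, ]] - theta[pairs[2L, ]]
  se <- sqrt(pmax(
    diag(V)[pairs[1L, ]] + diag(V)[pairs[2L, ]] -
      2 * V[cbind(pairs[1L, ], pairs[2L, ])], 0))
  out <- wald_tibble(stats::setNames(est, NULL), se, conf.level, exponentiate)
  out$term <- NULL
  tibble::tibble(treat1 = pairs[1L, ], treat2 = pairs[2L, ], out)
}

#' Component and treatment report of a component model
#'
#' The per-model report: component effects `beta` and composed treatment
#' effects `theta` versus the inactive/reference treatment, on the additive
#' and exponentiated scales. A combination treatment's row satisfies
#' `exp(theta) = prod(exp(beta))` over its components, i.e. on the OR scale
#' the combination effect is the product of its component ORs.
#'
#' @param fit a `cnma_fit`.
#' @param conf.level confidence level.
#' @return tibble with `level` (`"component"`/`"treatment"`), `term`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high` (additive scale) and
#'   `ratio`, `ratio.low`, `ratio.high` (exponentiated).
#' @export
component_table <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "cnma_fit"))
  comp <- tidy.cnma_fit(fit, "components", conf.level = conf.level)
  trt <- tidy.cnma_fit(fit, "treatments", conf.level = conf.level)
  out <- dplyr::bind_rows(
    dplyr::mutate(comp, level = "component", .before = 1L),
    dplyr::mutate(trt, level = "treatment", .before = 1L)
  )
  dplyr::mutate(out,
                ratio = exp(.data$estimate),
                ratio.low = exp(.data$conf.low),
                ratio.high = exp(.data$conf.high))
}

#' Plain-text forest table versus the reference
#'
#' Tabular rendering of the fitted treatment effects against the
#' reference/inactive treatment, formatted as `OR [low-high]` with a fixed
#' number of decimals (mean difference scale if `exponentiate = FALSE`).
#'
#' @param fit an `nma_fit` or `cnma_fit`.
#' @param exponentiate format as ratios (default).
#' @param digits decimals in the formatted column.
#' @param conf.level confidence level.
#' @return (invisibly) a tibble with `term` and the `formatted` column;
#'   printed as aligned text.
#' @export
forest_text <- function(fit, exponentiate = TRUE, digits = 2,
                        conf.level = 0.95) {
  dat <- if (inherits(fit, "cnma_fit")) {
    tidy.cnma_fit(fit, "treatments", conf.level = conf.level,
                  exponentiate = exponentiate)
  } else {
    tidy.nma_fit(fit, conf.level = conf.level, exponentiate = exponentiate)
  }
  ref <- if (inherits(fit, "cnma_fit")) fit$inactive else fit$reference
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  dat$formatted <- paste0(fmt(dat$estimate), " [", fmt(dat$conf.low), "-",
                          fmt(dat$conf.high), "]")
  width <- max(nchar(dat$term), nchar("Treatment"))
  header <- sprintf("%-*s  %s", width, "Treatment",
                    if (exponentiate) "OR (95% CI)" else "Effect (95% CI)")
  cat(header, "\n", sep = "")
  if (!is.null(ref)) cat(sprintf("(compared to %s)\n", ref))
  cat(sprintf("%-*s  %s", width, dat$term, dat$formatted), sep = "\n")
  invisible(dat[c("term", "estimate", "conf.low", "conf.high", "formatted")])
}

#' Model comparison table for standard / interaction / additive models
#'
#' Per-model heterogeneity statistics plus the nested Q-difference tests:
#' each sparser model against the standard model, and the additive model
#' against any interaction model. All comparisons use common-effect Q
#' statistics.
#'
#' @param standard an `nma_fit`.
#' @param additive a `cnma_fit` for the additive model.
#' @param interaction optional `cnma_fit` for an interaction model.
#' @return tibble with `model`, `Q`, `df`, `p.value`, `tau2` for the fits
#'   and rows `"<rich> vs <sparse>"` with the difference tests.
#' @export
compare_models <- function(standard, additive, interaction = NULL) {
  rows <- list(
    tibble::tibble(model = "standard", Q = standard$Q, df = standard$df_Q,
                   p.value = standard$p_Q, tau2 = standard$tau2)
  )
  if (!is.null(interaction)) {
    rows <- c(rows, list(
      tibble::tibble(model = "interaction", Q = interaction$Q,
                     df = interaction$df_Q, p.value = interaction$p_Q,
                     tau2 = interaction$tau2)))
  }
  rows <- c(rows, list(
    tibble::tibble(model = "additive", Q = additive$Q, df = additive$df_Q,
                   p.value = additive$p_Q, tau2 = additive$tau2)))

  tests <- list({
    t1 <- additivity_test(standard, additive)
    tibble::tibble(model = "additive vs standard", Q = t1$Q_diff,
                   df = t1$df, p.value = t1$p, tau2 = NA_real_)
  })
  if (!is.null(interaction)) {
    t2 <- additivity_test(standard, interaction)
    t3 <- compare_nested(interaction, additive)
    tests <- c(tests, list(
      tibble::tibble(model = "interaction vs standard", Q = t2$Q_diff,
                     df = t2$df, p.value = t2$p, tau2 = NA_real_),
      tibble::tibble(model = "additive vs interaction", Q = t3$Q_diff,
                     df = t3$df, p.value = t3$p, tau2 = NA_real_)))
  }
  dplyr::bind_rows(c(rows, tests))
}
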