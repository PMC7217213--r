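#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a standard NMA fit
#'
#' One row per treatment effect versus the reference (the reference row is
#' omitted), with Wald confidence limits on the additive scale or, with
#' `exponentiate = TRUE`, as odds/risk ratios.
#'
#' @param x an `nma_fit`.
#' @param conf.level confidence level.
#' @param exponentiate report `exp()` of estimates and limits.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `reference`.
#' @method tidy nma_fit
#' @export
tidy.nma_fit <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  keep <- setdiff(names(x$theta_hat), x$reference)
  out <- wald_tibble(x$theta_hat[keep], x$se_theta[keep], conf.level,
                     exponentiate)
  out$reference <- x$reference
  out
}

#' Tidy a component NMA fit
#'
#' @param x a `cnma_fit`.
#' @param type `"components"` (default) for the component effects `beta`,
#'   `"treatments"` for the composed treatment effects `theta = C beta`
#'   versus the inactive treatment (whose row is omitted when defined).
#' @inheritParams tidy.nma_fit
#' @return a tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @method tidy cnma_fit
#' @export
tidy.cnma_fit <- function(x, type = c("components", "treatments"),
                          conf.level = 0.95, exponentiate = FALSE, ...) {
  type <- match.arg(type)
  if (type == "components") {
    wald_tibble(x$beta_hat, sqrt(pmax(diag(x$cov_beta), 0)), conf.level,
                exponentiate)
  } else {
    keep <- setdiff(names(x$theta_hat), x$inactive)
    wald_tibble(x$theta_hat[keep],
                sqrt(pmax(diag(x$cov_theta)[keep], 0)),
                conf.level, exponentiate)
  }
}

wald_tibble <- function(est, se, conf.level, exponentiate) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    conf.low = unname(est - z * se), conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-row model summary of a standard NMA fit
#'
#' @param x an `nma_fit`.
#' @param ... unused.
#' @return a tibble with the model tag, effects model, heterogeneity
#'   statistic `Q` with `df` and `p.value`, `tau2`, `I2`, and the network
#'   sizes `n`, `m`, `k`, `n_a`.
#' @method glance nma_fit
#' @export
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, effects = x$effects,
    Q = x$Q, df = x$df_Q, p.value = x$p_Q,
    tau2 = x$tau2, I2 = x$I2,
    n = x$network$n, m = x$network$m, k = x$network$k, n_a = x$network$n_a
  )
}

#' @rdname glance.nma_fit
#' @method glance cnma_fit
#' @export
glance.cnma_fit <- function(x, ...) {
  out <- glance.nma_fit(x, ...)
  out$rank <- x$rank
  out$n_components <- length(x$beta_hat)
  out$disconnected <- isTRUE(x$disconnected)
  out
}

#' Forest-style plot of treatment (or component) effects
#'
#' @param object an `nma_fit` or `cnma_fit`.
#' @param type for `cnma_fit`, `"components"` or `"treatments"`.
#' @param exponentiate plot on the ratio scale (log-spaced axis).
#' @param conf.level confidence level.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nma_fit
#' @export
autoplot.nma_fit <- function(object, exponentiate = FALSE,
                             conf.level = 0.95, ...) {
  dat <- tidy(object, conf.level = conf.level, exponentiate = exponentiate)
  forest_gg(dat, exponentiate,
            xlab = if (exponentiate) "odds ratio" else "effect (additive scale)")
}

#' @rdname autoplot.nma_fit
#' @method autoplot cnma_fit
#' @export
autoplot.cnma_fit <- function(object, type = c("components", "treatments"),
                              exponentiate = FALSE, conf.level = 0.95, ...) {
  type <- match.arg(type)
  dat <- tidy(object, type = type, conf.level = conf.level,
              exponentiate = exponentiate)
  forest_gg(dat, exponentiate,
            xlab = paste(if (exponentiate) "odds ratio" else "effect",
                         "-", type))
}

forest_gg <- function(dat, exponentiate, xlab) {
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$term, .data$estimate),
    xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::geom_vline(xintercept = if (exponentiate) 1 else 0,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
  if (exponentiate) p <- p + ggplot2::scale_x_log10()
  p
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Standard NMA model (", x$effects, " effects), reference: ",
      x$reference, "\n", sep = "")
  print(glance.nma_fit(x))
  invisible(x)
}

#' @export
print.cnma_fit <- function(x, ...) {
  cat("Component NMA model: ", x$model,
      if (length(x$interactions))
        paste0(" (interactions: ", paste(x$interactions, collapse = ", "), ")"),
      ", ", x$effects, " effects",
      if (isTRUE(x$disconnected)) ", disconnected path", "\n", sep = "")
  print(glance.cnma_fit(x))
  invisible(x)
}
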