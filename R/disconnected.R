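#' Detect subnetworks of the comparison graph
#'
#' Connected components of the treatment graph (vertices = treatments,
#' edges = observed comparisons). One subnet means the standard connected
#' machinery applies; several mean no standard NMA exists, but component
#' models can still estimate contrasts lying in the row space of `Xa`
#' whenever the subnets share components.
#'
#' @param network an `nma_network`.
#' @param comps optional `component_structure`; if given, the rank of
#'   `Xa = B C` and an orthonormal basis of its row space (the estimable
#'   component contrasts) are included.
#' @param reference optional component label to report alongside.
#' @return an object of class `subnet_report`: `n_subnets`, `membership`
#'   (named vector treatment -> subnet id), and, when `comps` is supplied,
#'   `rank_Xa` and `estimable_contrasts` (basis matrix, one row per
#'   estimable direction).
#' @examples
#' net <- nma_network(tibble::tibble(
#'   study = c("s1", "s2", "s3"),
#'   treat1 = c("A", "B", "A+B"), treat2 = c("B+C", "A+C", "C"),
#'   effect = 0, se = 1
#' ))
#' detect_subnets(net)$n_subnets
#' @export
detect_subnets <- function(network, comps = NULL, reference = NULL) {
  stopifnot(inherits(network, "nma_network"))
  g <- network_graph(network)
  cmp <- igraph::components(g)
  membership <- cmp$membership[network$treatments]
  out <- list(n_subnets = cmp$no,
              membership = stats::setNames(as.integer(membership),
                                           network$treatments),
              rank_Xa = NULL, estimable_contrasts = NULL,
              reference = reference)
  if (!is.null(comps)) {
    Xa <- build_design(network, comps)
    s <- svd(Xa)
    keep <- s$d > 1e-10 * max(s$d, 0)
    basis <- t(s$v[, keep, drop = FALSE])
    colnames(basis) <- colnames(Xa)
    out$rank_Xa <- sum(keep)
    out$estimable_contrasts <- basis
  }
  structure(out, class = "subnet_report")
}

#' @export
print.subnet_report <- function(x, ...) {
  cat("Subnet report:", x$n_subnets,
      if (x$n_subnets == 1L) "connected component\n" else "connected components\n")
  for (i in seq_len(x$n_subnets)) {
    cat("  subnet ", i, ": ",
        paste(names(x$membership)[x$membership == i], collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$rank_Xa)) {
    cat("  rank(Xa) =", x$rank_Xa, "\n")
  }
  invisible(x)
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$contrasts[c("treat1", "treat2")],
    directed = FALSE,
    vertices = data.frame(name = network$treatments)
  )
}

n_subnets <- function(network) {
  igraph::components(network_graph(network))$no
}

#' Component NMA for (possibly) disconnected networks
#'
#' Fits the component model without requiring connectivity. If the
#' subnetworks share components, `Xa = B C` can still have full column rank
#' and all component effects are uniquely estimated; otherwise only
#' contrasts in the row space of `Xa` are estimable (query with
#' [estimable()] / [component_contrast()]).
#'
#' With a `reference` component, that component's column is dropped from
#' `C` and `Xa` before solving; the remaining coefficients are then
#' contrasts against the reference, which makes the reduced design
#' invertible whenever its rank equals its column count. Dropping a
#' reference column and solving the full design by pseudoinverse give
#' identical answers for contrasts estimable under both parameterisations.
#'
#' No additivity test is offered for a disconnected fit: without a standard
#' NMA model on the same network the additivity assumption is not testable,
#' and [additivity_test()] refuses such fits.
#'
#' On a connected network with full-rank design and no `reference`, the
#' result coincides exactly with [fit_cnma()].
#'
#' @inheritParams fit_cnma
#' @param reference optional component label used as reference (its column
#'   is omitted).
#' @return a `cnma_fit` with `disconnected = TRUE` bookkeeping; reported
#'   covariances are the weighted least-squares covariances of the chosen
#'   (possibly restricted) parameterisation.
#' @export
fit_disconnected <- function(network, comps, effects = c("common", "random"),
                             reference = NULL) {
  effects <- match.arg(effects)
  fit <- cnma_engine(network, comps, effects, allow_deficient = TRUE,
                     disconnected = TRUE, drop_component = reference)
  if (fit$rank < 1L) {
    rlang::abort("design matrix Xa has rank 0: nothing is estimable",
                 class = "cnma_identification_error")
  }
  fit$disconnected <- TRUE
  fit
}

#' Is a component contrast estimable?
#'
#' A linear combination `v` of component effects is estimable iff `v` lies
#' in the row space of the design matrix `Xa`, checked via the norm of the
#' residual of `v` after projection onto that row space (tolerance
#' `1e-10`).
#'
#' @param fit a `cnma_fit` (or a design matrix `Xa`).
#' @param contrast named numeric vector of component coefficients, e.g.
#'   `c(A = 1, B = -1)` for "A versus B"; unnamed components are zero.
#' @return `TRUE`/`FALSE`.
#' @export
estimable <- function(fit, contrast) {
  Xa <- if (is.matrix(fit)) fit else fit$X
  v <- contrast_vector(contrast, colnames(Xa))
  rowspace_residual(Xa, v) <= 1e-10 * max(1, sqrt(sum(v^2)))
}

#' Estimate a component contrast
#'
#' Point estimate, standard error and Wald confidence interval for a linear
#' combination of component effects. Works for rank-deficient (e.g.
#' disconnected) fits as long as the contrast is estimable: the minimum-norm
#' pseudoinverse solution gives the unique value of any estimable contrast.
#'
#' @inheritParams estimable
#' @param level confidence level.
#' @return one-row tibble with `contrast`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (additive scale).
#' @export
component_contrast <- function(fit, contrast, level = 0.95) {
  stopifnot(inherits(fit, "cnma_fit"))
  v <- contrast_vector(contrast, names(fit$beta_hat))
  if (rowspace_residual(fit$X, v) > 1e-10 * max(1, sqrt(sum(v^2)))) {
    rlang::abort(paste0("contrast ", contrast_label(contrast),
                        " is not estimable in this design"),
                 class = "cnma_estimability_error")
  }
  est <- sum(v * fit$beta_hat)
  se <- sqrt(max(drop(v %*% fit$cov_beta %*% v), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    contrast = contrast_label(contrast),
    estimate = est, std.error = se,
    conf.low = est - z * se, conf.high = est + z * se
  )
}

contrast_vector <- function(contrast, components) {
  if (is.null(names(contrast)) || any(!nzchar(names(contrast)))) {
    rlang::abort("`contrast` must be a named numeric vector of components",
                 class = "cnma_usage_error")
  }
  unknown <- setdiff(names(contrast), components)
  if (length(unknown)) {
    rlang::abort(paste0("unknown component(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "cnma_usage_error")
  }
  v <- stats::setNames(numeric(length(components)), components)
  v[names(contrast)] <- as.numeric(contrast)
  v
}

contrast_label <- function(contrast) {
  paste0(ifelse(contrast > 0, "+", ""), contrast, "*", names(contrast),
         collapse = " ")
}
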