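#' Fit an additive or interaction component NMA model
#'
#' The component model replaces the standard design `B` by `Xa = B %*% C`,
#' where `C` maps treatments to their components: a treatment's effect is
#' the sum of its component effects (additive scale), so equal components
#' cancel in comparisons. Estimation is weighted least squares,
#' `beta_hat = (Xa' W Xa)^+ Xa' W d`, with treatment effects
#' `theta_hat = C beta_hat` and fitted contrasts `delta_hat = Xa beta_hat`.
#' If `comps` carries interaction columns (from [add_interactions()]) the
#' same machinery yields the interaction CNMA model.
#'
#' Random effects: `tau2` is estimated by [estimate_tau2()] with this
#' model's hat matrix and degrees of freedom (`df_a = n_a - k - r`, `r` the
#' rank of `Xa`), the sampling variances enlarged and re-adjusted for
#' multi-arm studies, and the model refitted.
#'
#' @param network a connected `nma_network`.
#' @param comps a `component_structure` covering the network's treatments.
#' @param effects `"common"` or `"random"`.
#' @param allow_deficient if `FALSE` (default) a rank-deficient design
#'   (`rank(Xa) < c`) is an identification error naming the non-identified
#'   components; if `TRUE` the minimum-norm pseudoinverse solution is
#'   returned and only contrasts in the row space of `Xa` are meaningful
#'   (see [estimable()]).
#' @return an object of class `cnma_fit`: component effects `beta_hat` with
#'   `cov_beta`, treatment effects `theta_hat` (vs the inactive treatment)
#'   with `cov_theta`, fitted contrasts `delta_hat` with `cov_delta`, hat
#'   matrix `Ha`, the common-effect heterogeneity statistic `Q` with `df_Q`
#'   and `p_Q`, `tau2`, `I2`, the design `Xa` and its `rank`.
#' @examples
#' net <- nma_network(tibble::tibble(
#'   study = "s1", treat1 = "A", treat2 = "placebo", effect = 0.5, se = 1
#' ))
#' cs <- build_combination(net, inactive = "placebo")
#' fit_cnma(net, cs)$beta_hat
#' @export
fit_cnma <- function(network, comps, effects = c("common", "random"),
                     allow_deficient = FALSE) {
  effects <- match.arg(effects)
  if (n_subnets(network) > 1L) {
    rlang::abort(
      "the network is disconnected; use fit_disconnected()",
      class = "cnma_connectivity_error")
  }
  cnma_engine(network, comps, effects, allow_deficient = allow_deficient,
              disconnected = FALSE)
}

# shared CNMA estimation core (connected and disconnected paths)
cnma_engine <- function(network, comps, effects, allow_deficient,
                        disconnected, drop_component = NULL) {
  stopifnot(inherits(network, "nma_network"),
            inherits(comps, "component_structure"))
  C <- comps$C[network$treatments, , drop = FALSE]
  if (!is.null(drop_component)) {
    if (!drop_component %in% colnames(C)) {
      rlang::abort(paste0("reference component `", drop_component,
                          "` is not a component"),
                   class = "cnma_usage_error")
    }
    C <- C[, setdiff(colnames(C), drop_component), drop = FALSE]
  }
  B <- build_incidence(network)
  Xa <- B %*% C
  zero_col <- colSums(abs(Xa)) == 0
  if (any(zero_col) && !allow_deficient) {
    rlang::abort(paste0("component(s) never informative in any comparison: ",
                        paste(colnames(Xa)[zero_col], collapse = ", ")),
                 class = "cnma_identification_error")
  }
  r <- mat_rank(Xa)
  if (r < ncol(Xa) && !allow_deficient && !disconnected) {
    rlang::abort(paste0(
      "design matrix Xa has rank ", r, " < ", ncol(Xa),
      " components; non-identified: ",
      paste(nonidentified_components(Xa), collapse = ", "),
      " (set allow_deficient = TRUE to work with estimable contrasts)"),
      class = "cnma_identification_error")
  }

  d <- network$contrasts$effect
  w0 <- weight_vector(network)
  fit0 <- wls_project(Xa, w0, d)
  df_a <- network$n_a - network$k - r
  if (df_a < 0L) {
    rlang::abort("negative degrees of freedom for the component model",
                 class = "cnma_structural_error")
  }
  Qa <- sum(w0 * (d - fit0$delta)^2)
  p_a <- if (df_a > 0L) stats::pchisq(Qa, df_a, lower.tail = FALSE) else NA_real_

  tau2 <- if (effects == "random") estimate_tau2(network, fit0$H, Qa, df_a) else 0
  w <- if (effects == "random" && tau2 > 0) weight_vector(network, tau2) else w0
  fit <- if (identical(w, w0)) fit0 else wls_project(Xa, w, d)

  theta <- drop(C %*% fit$coef)
  cov_theta <- C %*% fit$coef_cov %*% t(C)
  inter <- grep("*", colnames(C), fixed = TRUE, value = TRUE)

  structure(
    list(
      network = network, comps = comps,
      model = if (length(inter)) "interaction" else "additive",
      interactions = inter, effects = effects,
      inactive = comps$inactive, reference_component = drop_component,
      beta_hat = fit$coef, cov_beta = fit$coef_cov,
      theta_hat = theta, cov_theta = cov_theta,
      delta_hat = stats::setNames(fit$delta, rownames(B)),
      cov_delta = fit$cov_delta, Ha = fit$H,
      Q = Qa, df_Q = df_a, p_Q = p_a,
      tau2 = tau2, I2 = i_squared(Qa, df_a),
      d = d, X = Xa, rank = r, disconnected = disconnected,
      weights = w, weights_common = w0
    ),
    class = "cnma_fit"
  )
}

# components touched by the null space of Xa (not separately identified)
nonidentified_components <- function(Xa, tol = 1e-10) {
  s <- svd(Xa)
  null_cols <- s$d <= tol * max(s$d, 0)
  if (ncol(Xa) > length(s$d)) {
    null_cols <- c(null_cols, rep(TRUE, ncol(Xa) - length(s$d)))
  }
  ns <- s$v[, null_cols, drop = FALSE]
  colnames(Xa)[rowSums(abs(ns)) > tol]
}

#' Heterogeneity statistic of a component model
#'
#' `Qa = (d - delta_hat_a)' W (d - delta_hat_a)` under common-effect
#' weights, with `df_a = n_a - k - r` degrees of freedom (`r` the rank of
#' the component design; `k - r` for two-arm-only networks).
#'
#' @param network the `nma_network` the model was fitted on.
#' @param fit a `cnma_fit`.
#' @return list with `Q`, `df`, `p`.
#' @export
q_cnma <- function(network, fit) {
  stopifnot(inherits(fit, "cnma_fit"))
  w0 <- weight_vector(network)
  f0 <- wls_project(fit$X, w0, network$contrasts$effect)
  df <- network$n_a - network$k - fit$rank
  if (df < 0L) {
    rlang::abort("negative degrees of freedom for the component model",
                 class = "cnma_structural_error")
  }
  Q <- sum(w0 * (network$contrasts$effect - f0$delta)^2)
  list(Q = Q, df = df,
       p = if (df > 0L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

#' Test the additivity assumption
#'
#' Compares the sparser component model against the richer standard NMA
#' model via the Pythagorean decomposition of the heterogeneity statistic:
#' `Qa - Q = (delta_hat_a - delta_hat_nma)' W (delta_hat_a - delta_hat_nma)`
#' on `n - r - 1` degrees of freedom. A small p-value indicates the
#' additive (or chosen interaction) structure does not explain the data as
#' well as giving every combination its own node.
#'
#' With `weights = "common"` (default) the comparison uses the
#' common-effect heterogeneity statistics, which is how the test is usually
#' reported alongside random-effects estimates. With `weights = "random"`
#' both models are re-projected under shared weights that include the
#' standard model's between-study variance, which keeps the test close to
#' its nominal size when heterogeneity is present.
#'
#' @param standard an `nma_fit`.
#' @param cnma a `cnma_fit` on the same network.
#' @param weights `"common"` or `"random"` (see Details).
#' @return a `cnma_model_comparison`: list with `Q_diff`, `df`, `p`, the
#'   compared model tags, and the verified Pythagorean gap.
#' @export
additivity_test <- function(standard, cnma,
                            weights = c("common", "random")) {
  stopifnot(inherits(standard, "nma_fit"), inherits(cnma, "cnma_fit"))
  weights <- match.arg(weights)
  network <- standard$network
  check_same_fit_basis(standard, cnma)
  if (isTRUE(cnma$disconnected)) {
    rlang::abort("additivity is not testable in a disconnected network",
                 class = "cnma_usage_error")
  }
  df <- network$n - cnma$rank - 1L
  d <- network$contrasts$effect
  if (weights == "common") {
    w <- standard$weights_common
    tau2_shared <- 0
  } else {
    tau2_shared <- if (standard$effects == "random") standard$tau2 else {
      f0 <- wls_project(standard$X, standard$weights_common, d)
      qs <- q_statistic(network, f0$delta, standard$weights_common)
      estimate_tau2(network, f0$H, qs$Q, qs$df)
    }
    w <- weight_vector(network, tau2_shared)
  }
  f_std <- wls_project(standard$X, w, d)
  f_add <- wls_project(cnma$X, w, d)
  Q_std <- sum(w * (d - f_std$delta)^2)
  Q_add <- sum(w * (d - f_add$delta)^2)
  Q_diff <- Q_add - Q_std
  gap <- abs(Q_diff - sum(w * (f_add$delta - f_std$delta)^2))
  if (gap > 1e-6 * max(1, Q_add)) {
    rlang::warn("Pythagorean identity violated beyond tolerance; results suspect")
  }
  new_model_comparison(Q_diff, df, rich = "standard", sparse = cnma$model,
                       weights = weights, tau2 = tau2_shared, gap = gap)
}

#' Compare two nested component models
#'
#' For a sparser model whose design column space is contained in a richer
#' model's (e.g. additive within an interaction model), the difference of
#' their common-effect heterogeneity statistics is chi-square with degrees
#' of freedom equal to the rank difference of the designs.
#'
#' @param rich,sparse two `cnma_fit` objects on the same network, with
#'   `span(X_sparse)` contained in `span(X_rich)`.
#' @return a `cnma_model_comparison`.
#' @export
compare_nested <- function(rich, sparse) {
  stopifnot(inherits(rich, "cnma_fit"), inherits(sparse, "cnma_fit"))
  check_same_fit_basis(rich, sparse)
  if (mat_rank(cbind(sparse$X, rich$X)) > rich$rank) {
    rlang::abort("models are not nested: sparse design not in the rich design's span",
                 class = "cnma_usage_error")
  }
  d <- rich$network$contrasts$effect
  w <- rich$weights_common
  Q_rich <- sum(w * (d - wls_project(rich$X, w, d)$delta)^2)
  Q_sparse <- sum(w * (d - wls_project(sparse$X, w, d)$delta)^2)
  new_model_comparison(Q_sparse - Q_rich, rich$rank - sparse$rank,
                       rich = paste0(rich$model,
                                     if (length(rich$interactions))
                                       paste0("(", paste(rich$interactions,
                                                         collapse = ","), ")")
                                     else ""),
                       sparse = sparse$model, weights = "common", tau2 = 0)
}

new_model_comparison <- function(Q_diff, df, rich, sparse, weights,
                                 tau2 = 0, gap = 0) {
  Q_diff <- max(Q_diff, 0)
  structure(
    list(Q_diff = Q_diff, df = as.integer(df),
         p = if (df > 0) stats::pchisq(Q_diff, df, lower.tail = FALSE)
             else NA_real_,
         models = c(rich = rich, sparse = sparse),
         weights = weights, tau2_shared = tau2, pythagoras_gap = gap),
    class = "cnma_model_comparison"
  )
}

#' @export
print.cnma_model_comparison <- function(x, ...) {
  cat("Model comparison (", x$models[["rich"]], " vs ", x$models[["sparse"]],
      ", ", x$weights, " weights)\n", sep = "")
  cat(sprintf("  Q difference = %.4f, df = %d, p = %s\n", x$Q_diff, x$df,
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 4)))
  invisible(x)
}

check_same_fit_basis <- function(a, b) {
  na <- a$network; nb <- b$network
  if (!identical(na$contrasts[c("study", "treat1", "treat2", "effect")],
                 nb$contrasts[c("study", "treat1", "treat2", "effect")])) {
    rlang::abort("fits are not based on the same network data",
                 class = "cnma_usage_error")
  }
  if (max(abs(a$weights_common - b$weights_common)) > 1e-10) {
    rlang::abort("fits do not share the same common-effect weights",
                 class = "cnma_usage_error")
  }
  invisible(TRUE)
}
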