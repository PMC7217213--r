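#' Fit the standard network meta-analysis model
#'
#' Weighted least-squares NMA in the graph-theoretical formulation: with
#' design matrix `X = B` (the edge-vertex incidence matrix) and diagonal
#' weight matrix `W`, the consistent contrast estimates are
#' `delta_hat = X (X'WX)^+ X' W d = H d`, where `(.)^+` is the Moore-Penrose
#' pseudoinverse of the weighted graph Laplacian and `H` the hat matrix.
#' The standard model treats every distinct (combination) treatment as its
#' own node, i.e. it is the full interaction model.
#'
#' For `effects = "random"`, the between-study variance is first estimated
#' by the method of moments ([estimate_tau2()]), added to each raw sampling
#' variance, the multi-arm adjustment redone, and the model refitted with
#' the enlarged variances. The heterogeneity statistic `Q` and its `I2`
#' always refer to the common-effect weights.
#'
#' @param network a connected `nma_network`.
#' @param effects `"common"` or `"random"`.
#' @param reference treatment label the treatment effects `theta_hat` are
#'   expressed against; defaults to the first treatment in network order.
#' @return an object of class `nma_fit` with elements `delta_hat`,
#'   `cov_delta`, `H` (hat matrix), `theta_hat` and `se_theta` (vs the
#'   reference), `cov_theta` (Laplacian pseudoinverse), `Q`, `df_Q`, `p_Q`,
#'   `tau2`, `I2`, and bookkeeping fields.
#' @examples
#' net <- nma_network(tibble::tibble(
#'   study = c("s1", "s2", "s3"),
#'   treat1 = c("A", "B", "A"), treat2 = c("B", "C", "C"),
#'   effect = c(1, 1, 2), se = 1
#' ))
#' fit <- fit_nma(net, reference = "C")
#' fit$theta_hat
#' @seealso [fit_cnma()] for the component (additive/interaction) models.
#' @export
fit_nma <- function(network, effects = c("common", "random"),
                    reference = NULL) {
  stopifnot(inherits(network, "nma_network"))
  effects <- match.arg(effects)
  if (n_subnets(network) > 1L) {
    rlang::abort(
      "the network is disconnected; use detect_subnets() and fit_disconnected()",
      class = "cnma_connectivity_error")
  }
  reference <- reference %||% network$treatments[[1L]]
  if (!reference %in% network$treatments) {
    rlang::abort(paste0("reference `", reference, "` is not a treatment"),
                 class = "cnma_usage_error")
  }

  B <- build_incidence(network)
  d <- network$contrasts$effect
  w0 <- weight_vector(network)

  fit0 <- wls_project(B, w0, d)
  qs <- q_statistic(network, fit0$delta, w0)
  tau2 <- if (effects == "random") estimate_tau2(network, fit0$H, qs$Q, qs$df) else 0

  w <- if (effects == "random" && tau2 > 0) weight_vector(network, tau2) else w0
  fit <- if (identical(w, w0)) fit0 else wls_project(B, w, d)

  L_plus <- fit$coef_cov              # (B'WB)^+ : Laplacian pseudoinverse
  theta <- drop(fit$coef)
  theta <- theta - theta[[reference]]
  v_ref <- diag(L_plus) + L_plus[reference, reference] -
    2 * L_plus[, reference]
  se_theta <- sqrt(pmax(v_ref, 0))

  structure(
    list(
      network = network, model = "standard", effects = effects,
      reference = reference,
      delta_hat = stats::setNames(fit$delta, rownames(B)),
      cov_delta = fit$cov_delta, H = fit$H,
      theta_hat = theta, se_theta = se_theta, cov_theta = L_plus,
      Q = qs$Q, df_Q = qs$df, p_Q = qs$p,
      tau2 = tau2, I2 = i_squared(qs$Q, qs$df),
      d = d, X = B, weights = w, weights_common = w0
    ),
    class = "nma_fit"
  )
}

# weighted least-squares projection machinery shared by all models:
# coef = (X'WX)^+ X'W d, delta = X coef, H = X (X'WX)^+ X' W
wls_project <- function(X, w, d) {
  XtW <- t(X * w)
  G <- pinv(XtW %*% X)                 # (X'WX)^+
  coef <- drop(G %*% (XtW %*% d))
  names(coef) <- colnames(X)
  XG <- X %*% G
  list(coef = coef, coef_cov = G,
       delta = drop(X %*% coef),
       H = XG %*% XtW,
       cov_delta = XG %*% t(X))
}

#' Cochran Q statistic of the standard NMA model
#'
#' `Q = (d - delta_hat)' W (d - delta_hat)` with common-effect weights and
#' `n_a - k - (n - 1)` degrees of freedom (`n_a` total arms, `k` studies,
#' `n` treatments); for two-arm-only networks this is `k - (n - 1)`.
#'
#' @param network an `nma_network`.
#' @param delta_hat fitted consistent contrasts.
#' @param W diagonal weight matrix or weight vector (common-effect weights).
#' @return list with `Q`, `df`, and the chi-square upper-tail `p`.
#' @export
q_statistic <- function(network, delta_hat, W) {
  w <- if (is.matrix(W)) diag(W) else as.numeric(W)
  df <- network$n_a - network$k - (network$n - 1L)
  if (df < 0L) {
    rlang::abort("negative degrees of freedom: over-parameterised network",
                 class = "cnma_structural_error")
  }
  resid <- network$contrasts$effect - as.numeric(delta_hat)
  Q <- sum(w * resid^2)
  list(Q = Q, df = df,
       p = if (df > 0L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

#' Method-of-moments between-study variance
#'
#' Multivariate moment estimator
#' `tau2 = max((Q - df) / tr((I - H) U W), 0)`, where `U` is the
#' block-diagonal matrix obtained from `0.5 * B B'` by keeping, for each
#' study, the block of its own contrasts and zeroing everything else, and
#' `W` holds the common-effect weights. For two-arm-only networks `U` is the
#' identity and the estimator reduces to the generalised DerSimonian-Laird
#' moment equation.
#'
#' @param network an `nma_network`.
#' @param H hat matrix of the fitted design under common-effect weights.
#' @param Q,df the heterogeneity statistic and degrees of freedom of that
#'   design (from [q_statistic()] or [q_cnma()]).
#' @return the truncated non-negative estimate of `tau2`.
#' @export
estimate_tau2 <- function(network, H, Q, df) {
  if (df <= 0L) return(0)
  U <- block_u(network)
  w <- weight_vector(network)
  M <- diag(network$m) - H
  denom <- sum(M * t(U * rep(w, each = network$m)))  # tr((I - H) U W)
  if (denom <= 0) {
    rlang::abort("tr((I - H) U W) <= 0: degenerate design for tau2 estimation",
                 class = "cnma_structural_error")
  }
  max((Q - df) / denom, 0)
}

# per-study block diagonal of 0.5 B B'
block_u <- function(network) {
  B <- build_incidence(network)
  U <- 0.5 * tcrossprod(B)
  same_study <- outer(network$contrasts$study, network$contrasts$study, `==`)
  U * same_study
}

#' Higgins I-squared from Q and df
#'
#' `I2 = max(0, (Q - df) / Q)`, the proportion of total variability
#' attributed to heterogeneity/inconsistency. Undefined (`NA`) for `df = 0`.
#'
#' @param Q heterogeneity statistic.
#' @param df its degrees of freedom.
#' @return `I2` in `[0, 1]`, or `NA` when `df = 0`.
#' @export
i_squared <- function(Q, df) {
  if (df <= 0) return(NA_real_)
  if (Q <= 0) return(0)
  max(0, (Q - df) / Q)
}
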