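#' Adjust multi-arm standard errors
#'
#' A `p`-arm study reports `p(p-1)/2` correlated pairwise contrasts. To use
#' them in a weighted least-squares network model that treats contrasts as
#' independent, the standard errors are enlarged so that the study's
#' contribution to the network information matrix (its weighted graph
#' Laplacian) equals the information matrix of the joint arm-level
#' generalised least-squares model.
#'
#' The construction: arm variances `s_t` are recovered by least squares from
#' the contrast variances (`v_jk = s_j + s_k`); the study Laplacian `L` is
#' the Moore-Penrose inverse of the double-centred matrix `-0.5 * Jc V Jc`
#' (contrast variances read as resistance distances); the adjusted weight of
#' contrast `(j, k)` is `-L[j, k]` and the adjusted variance its inverse.
#' Two-arm studies are left untouched (`se_adj = se`). The operation is
#' idempotent: adjusted values are always recomputed from the raw `se`.
#'
#' @param network an `nma_network` object.
#' @param tau2 non-negative between-study variance added to every raw
#'   sampling variance before the adjustment (used by random-effects fits).
#' @param tol relative tolerance for the consistency of the observed contrast
#'   variances with an arm-based decomposition; beyond it the least-squares
#'   reconciliation is used with a warning.
#' @return the network with its `se_adj` column set.
#' @export
adjust_multiarm <- function(network, tau2 = 0, tol = 1e-8) {
  stopifnot(inherits(network, "nma_network"), tau2 >= 0)
  d <- network$contrasts
  v <- d$se^2 + tau2
  se_adj <- sqrt(v)
  for (s in network$studies[network$arms > 2L]) {
    idx <- which(d$study == s)
    se_adj[idx] <- sqrt(adjusted_variances(
      v[idx], d$treat1[idx], d$treat2[idx], study = s, tol = tol))
  }
  network$contrasts$se_adj <- se_adj
  network
}

# Adjusted contrast variances for one multi-arm study.
# v: raw contrast variances; t1/t2: endpoint labels per contrast.
adjusted_variances <- function(v, t1, t2, study = "?", tol = 1e-8) {
  arms <- sort(unique(c(t1, t2)), method = "radix")
  p <- length(arms)
  m_s <- length(v)
  A <- matrix(0, m_s, p, dimnames = list(NULL, arms))
  A[cbind(seq_len(m_s), match(t1, arms))] <- 1
  A[cbind(seq_len(m_s), match(t2, arms))] <- 1
  s_arm <- drop(solve(crossprod(A), crossprod(A, v)))
  vhat <- drop(A %*% s_arm)
  if (max(abs(vhat - v)) > tol * max(v)) {
    rlang::warn(paste0(
      "study ", study, ": contrast variances are not consistent with an ",
      "arm-based decomposition; using the least-squares reconciliation"))
  }
  if (any(s_arm <= 0)) {
    rlang::abort(paste0("study ", study, ": implied arm variance is not positive"),
                 class = "cnma_validation_error")
  }
  V <- matrix(0, p, p)
  ij <- cbind(match(t1, arms), match(t2, arms))
  V[ij] <- vhat
  V[ij[, 2:1, drop = FALSE]] <- vhat
  Jc <- diag(p) - 1 / p
  L <- pinv(-0.5 * Jc %*% V %*% Jc)
  w <- -L[ij]
  if (any(w <= 0)) {
    rlang::abort(paste0("study ", study, ": degenerate multi-arm weight structure"),
                 class = "cnma_validation_error")
  }
  1 / w
}

#' Inverse-variance weight matrix
#'
#' Diagonal weight matrix of the network. For `tau2 = 0` the weights are the
#' inverses of the multi-arm adjusted sampling variances. For `tau2 > 0` the
#' between-study variance is added to each raw sampling variance first and
#' the multi-arm adjustment is redone on the enlarged variances, so
#' random-effects weights honour the same information-matrix contract.
#'
#' @param network an `nma_network` object.
#' @param tau2 non-negative between-study variance.
#' @return an `m x m` diagonal matrix of weights.
#' @export
build_weights <- function(network, tau2 = 0) {
  w <- weight_vector(network, tau2)
  diag(w, nrow = length(w))
}

weight_vector <- function(network, tau2 = 0) {
  net <- if (tau2 > 0) adjust_multiarm(network, tau2 = tau2) else network
  1 / net$contrasts$se_adj^2
}
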