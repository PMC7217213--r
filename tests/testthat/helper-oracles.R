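# Independent dense-algebra oracles. These deliberately avoid the package's
# own pinv()/wls_project() machinery: pseudoinverses come from MASS::ginv.

oracle_wls <- function(X, w, d) {
  X <- as.matrix(X)
  W <- diag(w, nrow = length(w))
  G <- MASS::ginv(t(X) %*% W %*% X)
  beta <- unname(drop(G %*% t(X) %*% W %*% d))
  list(beta = beta, delta = unname(drop(X %*% beta)),
       H = X %*% G %*% t(X) %*% W, cov_beta = G,
       cov_delta = X %*% G %*% t(X))
}

# information matrix (full p x p Laplacian) of the joint arm-level GLS model
# with arm variances s: contrasts vs arm 1 have covariance diag(s[-1]) + s[1]
oracle_arm_gls_laplacian <- function(s) {
  p <- length(s)
  D <- cbind(-1, diag(p - 1L))
  Sigma <- diag(s[-1L], nrow = p - 1L) + s[1L]
  t(D) %*% solve(Sigma) %*% D
}

# study-level Laplacian implied by treating the adjusted contrasts as
# independent with weights 1/se_adj^2
study_laplacian <- function(se_adj, t1, t2, arms) {
  m_s <- length(se_adj)
  Bs <- matrix(0, m_s, length(arms))
  Bs[cbind(seq_len(m_s), match(t1, arms))] <- 1
  Bs[cbind(seq_len(m_s), match(t2, arms))] <- -1
  t(Bs) %*% diag(1 / se_adj^2, nrow = m_s) %*% Bs
}
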