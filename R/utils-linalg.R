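#' Moore-Penrose pseudoinverse
#'
#' Pseudoinverse via singular value decomposition. Singular values below
#' `tol` times the largest singular value are treated as exact zeros, which
#' keeps graph Laplacians (exact rank `n - 1` on connected networks) and
#' rank-deficient component designs numerically stable.
#'
#' @param m numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudoinverse of `m`.
#' @keywords internal
#' @noRd
pinv <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (length(m) == 0L) return(t(m))
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(m), nrow(m), dimnames = rev(dimnames(m))))
  }
  out <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  dimnames(out) <- list(colnames(m), rownames(m))
  out
}

# numerical rank with the same relative tolerance as pinv()
mat_rank <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (length(m) == 0L) return(0L)
  d <- svd(m, nu = 0, nv = 0)$d
  sum(d > tol * max(d, 0))
}

# residual norm of v after projection onto the row space of x;
# ~0 iff v is a linear combination of the rows of x
rowspace_residual <- function(x, v) {
  v <- as.numeric(v)
  xt <- t(as.matrix(x))
  proj <- xt %*% (pinv(xt) %*% v)
  sqrt(sum((v - proj)^2))
}
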