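# Small internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Symmetrize and floor eigenvalues so a covariance estimate is usable
# downstream regardless of rounding noise in the fit.
#' @keywords internal
#' @noRd
make_psd <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  (S + t(S)) / 2
}

# Moore-Penrose pseudo-inverse via SVD; tolerance relative to the largest
# singular value, as in MASS::ginv.
#' @keywords internal
#' @noRd
pinv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Draw n samples from N(mean, Sigma) using a Cholesky root (with a small
# jitter fallback for semi-definite Sigma).
#' @keywords internal
#' @noRd
rmvn <- function(n, mean, Sigma) {
  d <- length(mean)
  R <- tryCatch(chol(Sigma), error = function(e) chol(Sigma + diag(1e-10, d)))
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% R, 2, mean, `+`)
}

# Log-density of y under N(mu, S) using a Cholesky factorization.
#' @keywords internal
#' @noRd
dmvn_log <- function(y, mu, S) {
  d <- length(y)
  R <- chol(S)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
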