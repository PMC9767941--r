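#' @keywords internal
"_PACKAGE"

# Smallest p-value retained before taking logs anywhere in the package.
P_FLOOR <- 1e-300

#' Two-sided p-value of a T statistic
#'
#' Upper-tail probability of a 1-df chi-squared variable evaluated at `t^2`,
#' i.e. the two-sided normal p-value of a GWAS T statistic.
#'
#' @param t Numeric vector of T statistics.
#' @return Numeric vector of p-values in (0, 1].
#' @export
p_from_t <- function(t) {
  stats::pchisq(t * t, df = 1L, lower.tail = FALSE)
}

# Upper-tail chi-squared probability (the "F" used throughout: survival
# function, not the CDF).
chisq_sf <- function(x, df) stats::pchisq(x, df = df, lower.tail = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Nearest positive-definite repair of a correlation matrix
#'
#' Floors the eigenvalues of a symmetric matrix at `eps`, reconstructs, and
#' rescales to unit diagonal. Used to keep estimated background-correlation
#' matrices invertible in the presence of near-duplicate studies.
#'
#' @param S Symmetric matrix.
#' @param eps Eigenvalue floor (default `1e-6`).
#' @return Repaired symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_pd <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values > eps)) return(S)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

# Quadratic forms t' Psi^{-1} t for the rows of a matrix, via one solve.
row_quadform <- function(Tmat, Psi) {
  rowSums((Tmat %*% solve(Psi)) * Tmat)
}

# sign() with sign(0) = +1, applied elementwise.
sign_pos <- function(x) ifelse(x >= 0, 1, -1)

# Mean of a 1-df chi-squared variable conditional on being <= q. Uses the
# identity x * f_{chi2,1}(x) = f_{chi2,3}(x), so
# E[X 1(X<=q)] = F_{chi2,3}(q).
chi2_1_trunc_mean <- function(q) {
  stats::pchisq(q, df = 3L) / stats::pchisq(q, df = 1L)
}

# Draws n rows from N(0, Sigma); Cholesky when positive definite, symmetric
# eigen square root otherwise (covers PSD-singular effect covariances).
rmvn <- function(n, Sigma) {
  K <- nrow(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  })
  matrix(stats::rnorm(n * K), n, K) %*% L
}

# Exchangeable correlation matrix with off-diagonal rho.
exch_corr <- function(K, rho) {
  S <- matrix(rho, K, K)
  diag(S) <- 1
  S
}

`%||%` <- function(a, b) if (is.null(a)) b else a
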