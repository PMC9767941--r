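#' Eigen-projection model for the multi-trait effect statistic
#'
#' Builds an uncorrelated null space from the background-correlation
#' matrix: the top R eigenvectors of `Psi`, with R the smallest number
#' whose cumulative eigenvalues reach `var_threshold` of the trace. Under
#' a null `t ~ N(0, Psi)`, each scaled projection `t^T V_i / sqrt(g_i)`
#' has unit variance and the projections are uncorrelated.
#'
#' @param Psi Symmetric PSD background-correlation matrix.
#' @param var_threshold Cumulative eigenvalue fraction to retain (default
#'   0.95).
#' @return Object of class `mte_model`: list with `V` (K x R), `g`
#'   (eigenvalues), `R`, `null_skew` (`2 * sqrt(2)`).
#' @export
fit_mte_model <- function(Psi, var_threshold = 0.95) {
  Psi <- as.matrix(Psi)
  if (max(abs(Psi - t(Psi))) > 1e-8) stop("Psi must be symmetric")
  e <- eigen(Psi, symmetric = TRUE)
  R <- which(cumsum(e$values) >= var_threshold * sum(e$values))[1L]
  V <- e$vectors[, seq_len(R), drop = FALSE]
  # reproducible eigenvector signs: largest-magnitude entry positive
  for (i in seq_len(R)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) V[, i] <- -V[, i]
  }
  structure(list(V = V, g = e$values[seq_len(R)], R = R,
                 null_skew = 2 * sqrt(2)),
            class = "mte_model")
}

#' Multi-trait effect statistic of one variant
#'
#' Projects the variant's K T statistics onto the uncorrelated null space
#' of the background-correlation matrix, squares the scaled projections,
#' and returns `2 * sqrt(2)` minus their skewness (third standardized
#' moment, population formula). Under the null the squared projections
#' are independent 1-df chi-squared variables whose skewness is exactly
#' `2 * sqrt(2)`, so the statistic is centered at zero; large positive
#' values indicate effects spread over many independent trait directions
#' (low skewness), and `MTE < 0` indicates insufficient evidence of a
#' multi-trait effect.
#'
#' @param t_vec K-vector of T statistics of a variant.
#' @param model An [fit_mte_model()] with at least 3 retained components.
#' @return The MTE value.
#' @export
mte <- function(t_vec, model) {
  if (model$R < 3L) stop("fewer than 3 components: skewness unstable")
  pt <- drop(t_vec %*% model$V) / sqrt(model$g)
  x <- pt * pt
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  # relative guard: equal projections have zero skewness by definition
  skew <- if (m2 <= 1e-14 * mean(x)^2) 0 else mean(xc^3) / m2^1.5
  model$null_skew - skew
}

#' Power-gain ratio between two GWASs from mean chi-squared statistics
#'
#' `(E(chi2_a) - intercept_a) / (E(chi2_b) - intercept_b)`: the ratio of
#' true-signal excesses after removing each study's confounding intercept
#' (e.g. an LD-score regression intercept).
#'
#' @param mean_chi2_a,mean_chi2_b Mean chi-squared statistics.
#' @param intercept_a,intercept_b Null intercepts.
#' @return The power ratio.
#' @export
power_gain_ratio <- function(mean_chi2_a, intercept_a,
                             mean_chi2_b, intercept_b) {
  num <- mean_chi2_a - intercept_a
  den <- mean_chi2_b - intercept_b
  if (den <= 0) stop("non-positive denominator excess")
  num / den
}

#' Fisher's combined probability test
#'
#' `T_F = -2 sum(log(p))`, chi-squared with `2 * length(p)` degrees of
#' freedom under the null of independent uniform p-values.
#'
#' @param p_list Vector of independent p-values in (0, 1]; zero or
#'   negative entries are floored at 1e-300 with a warning.
#' @return List with `T_F`, `df`, `p`.
#' @export
fisher_combined <- function(p_list) {
  if (any(p_list <= 0)) {
    warning("non-positive p-values floored at 1e-300")
    p_list <- pmax(p_list, P_FLOOR)
  }
  stopifnot(all(p_list <= 1))
  T_F <- -2 * sum(log(p_list))
  df <- 2L * length(p_list)
  list(T_F = T_F, df = df, p = chisq_sf(T_F, df))
}
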