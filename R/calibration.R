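#' Simulate null T statistics under a background-correlation matrix
#'
#' Draws `NS` independent K-vectors from `N(0, Psi)` (positive-definite
#' repair is applied first when needed). These simulated statistics feed
#' the empirical calibration of the truncated Wald scan.
#'
#' @param Psi K x K background-correlation matrix.
#' @param NS Number of draws (at least 1e4; calibration is unreliable
#'   below that).
#' @param seed Integer seed.
#' @return NS x K matrix of null T statistics.
#' @export
simulate_null_panel <- function(Psi, NS, seed = 1L) {
  if (NS < 1e4) stop("NS < 1e4: calibration would be unreliable")
  Psi <- nearest_pd(as.matrix(Psi))
  set.seed(seed)
  rmvn(NS, Psi)
}

#' Effective number of independent tests of a null p-value column
#'
#' Fits the `Neff` that makes the Tippett transform
#' `1 - (1 - p)^Neff` map the column's lower empirical quantiles onto the
#' uniform distribution: least squares on the log scale over quantile
#' levels `10^-1 ... 10^-4` (restricted to levels estimable from the
#' column size). Exact when the column is the minimum of `Neff`
#' independent uniforms; `Neff ~ 1` for an already-uniform column.
#'
#' An empty subset carries no evidence, so a missing entry is counted as
#' p = 1 rather than removed: this makes the fitted correction
#' unconditional, which is what comparability of all threshold columns at
#' one alpha requires (a rarely non-missing deep column converges to the
#' min-p column's correction, not to "no correction").
#'
#' @param p_column Vector of simulated null combined p-values (`NA` counts
#'   as 1; at least 1e4 entries required).
#' @return `Neff >= 1`.
#' @export
estimate_n_independent <- function(p_column) {
  p_column[is.na(p_column)] <- 1
  p <- sort(p_column)
  n <- length(p)
  if (n < 1e4) stop("fewer than 1e4 null p-values")
  # quantile levels from 1e-1 down as deep as the sample supports (>= 10
  # entries below): comparability of the threshold columns matters most at
  # the depths where study-wide selection happens
  u <- 10^seq(-1, log10(max(10 / n, 1e-6)), by = -0.25)
  u <- u[u * n >= 10]
  qhat <- p[pmax(1L, ceiling(u * n))]
  u <- u[qhat < 0.99]   # levels inside the column's support
  qhat <- qhat[qhat < 0.99]
  if (length(u) < 3L) stop("column support too thin to fit Neff")
  qhat <- pmax(qhat, P_FLOOR)
  obj <- function(log_neff) {
    adj <- -expm1(exp(log_neff) * log1p(-qhat))
    sum((log(pmax(adj, P_FLOOR)) - log(u))^2)
  }
  fit <- stats::optimize(obj, interval = c(log(1e-2), log(1e6)))
  max(1, exp(fit$minimum))
}

#' Tippett adjustment of a p-value
#'
#' `1 - (1 - p)^Neff`, computed in log1p space so tiny p-values keep full
#' precision. Exact multiple-testing correction for the minimum of `Neff`
#' independent uniform p-values.
#'
#' @param p P-value(s) in `[0, 1]` (`NA` passes through).
#' @param Neff Effective number of independent tests (>= 0).
#' @return Adjusted p-value(s).
#' @export
tippett_adjust <- function(p, Neff) {
  -expm1(Neff * log1p(-p))
}

#' Fit quantile-specific calibration coefficients from a simulated null
#'
#' Given the simulated null values of a statistic that should be uniform
#' (e.g. the row minima of the adjusted truncated-Wald matrix), computes
#' on a log-spaced quantile grid `u` the multiplicative coefficient
#' `c(u) = u / qhat_null(u)` that maps the empirical null quantile back to
#' the uniform quantile. The curve is stored as log-log linear
#' interpolation with constant extrapolation of `c` beyond the grid ends;
#' applying it (see [apply_calibration()]) makes the null uniform while
#' preserving significance order.
#'
#' @param null_min_p Vector of simulated null statistics in (0, 1].
#' @param n_grid Number of log-spaced grid points (default 2000, plus a
#'   mirrored upper-tail grid and deciles; the null-min CDF has kinks at
#'   component-support boundaries that a coarse grid would interpolate
#'   across).
#' @return Object of class `coef_curve` (list with `log_u`, `log_c`).
#' @export
fit_quantile_coefficients <- function(null_min_p, n_grid = 2000L) {
  p <- sort(null_min_p[!is.na(null_min_p)])
  n <- length(p)
  if (n < 100L || p[1] == p[n]) stop("degenerate null sample")
  # log-spaced toward 0 for the significance tail (but only down to levels
  # with >= 30 supporting points: extreme order statistics are stochastically
  # small and would bias the tail coefficient upward), mirrored log spacing
  # toward 1 (the null-min CDF is strongly curved near its upper end), plus
  # deciles
  u_min <- min(30 / n, 0.1)
  u <- sort(unique(c(10^seq(log10(u_min), 0, length.out = n_grid),
                     1 - 10^seq(log10(1 / n), log10(0.5),
                                length.out = n_grid %/% 4L),
                     seq(0.1, 0.9, by = 0.1), 1)))
  qhat <- pmax(p[pmax(1L, ceiling(u * n))], P_FLOOR)
  # strictly increasing null quantiles so the calibration map is invertible
  keep <- !duplicated(qhat)
  u <- u[keep]; qhat <- qhat[keep]
  log_u <- log(u); log_q <- log(qhat)
  # tail extrapolation: constant log-log slope fitted over the deepest
  # stable decade (with near-independent scan columns the coefficient is
  # still rising at the smallest estimable quantile, so a constant ratio
  # would under-correct; single grid points are too noisy to anchor)
  deep <- which(u <= 10 * u_min)
  if (length(deep) < 3L) deep <- seq_len(min(5L, length(u)))
  fit <- stats::lm.fit(cbind(1, log_q[deep]), log_u[deep])
  structure(list(log_u = log_u, log_c = log_u - log_q, log_q = log_q,
                 tail_intercept = fit$coefficients[[1L]],
                 tail_slope = fit$coefficients[[2L]]),
            class = "coef_curve")
}

#' Evaluate a calibration-coefficient curve
#'
#' @param object A `coef_curve` from [fit_quantile_coefficients()].
#' @param u Quantile levels in (0, 1].
#' @param ... Unused.
#' @return Coefficients `c(u)` (constant extrapolation outside the grid).
#' @export
predict.coef_curve <- function(object, u, ...) {
  exp(stats::approx(object$log_u, object$log_c, xout = log(pmax(u, P_FLOOR)),
                    rule = 2)$y)
}

#' Apply a calibration curve to a p-value vector
#'
#' Each p-value is multiplied by the quantile-specific coefficient of the
#' fitted curve, evaluated at the value's position on the null quantile
#' grid (log-log interpolation of the uniform level `u` over the null
#' quantile `qhat(u)`). On the grid this maps the simulated null exactly
#' onto the uniform quantiles; between and beyond grid points the
#' correction is multiplicative with a constant tail ratio, so the map is
#' strictly monotone and calibration preserves significance order. A
#' running maximum over the sorted values guards the monotone contract
#' numerically; results are clipped to (0, 1].
#'
#' @param p_vec P-values to calibrate.
#' @param coef_curve A `coef_curve` from [fit_quantile_coefficients()].
#' @return Calibrated p-values.
#' @export
apply_calibration <- function(p_vec, coef_curve) {
  lp <- log(pmax(p_vec, P_FLOOR))
  lu <- stats::approx(coef_curve$log_q, coef_curve$log_u, xout = lp,
                      ties = "ordered")$y
  # constant multiplicative coefficient beyond the grid ends
  nq <- length(coef_curve$log_q)
  lo <- lp < coef_curve$log_q[1L]
  hi <- lp > coef_curve$log_q[nq]
  if (any(lo)) {
    a <- coef_curve$tail_intercept %||%
      (coef_curve$log_u[1L] - coef_curve$log_q[1L])
    b <- coef_curve$tail_slope %||% 1
    # anchor at the first grid point so the map stays continuous
    shift <- coef_curve$log_u[1L] - (a + b * coef_curve$log_q[1L])
    lu[lo] <- a + b * lp[lo] + shift
  }
  lu[hi] <- lp[hi] + (coef_curve$log_u[nq] - coef_curve$log_q[nq])
  out <- exp(lu)
  ord <- order(p_vec)
  out[ord] <- cummax(out[ord])
  clamp(out, P_FLOOR, 1)
}

#' Build the empirical calibration model for a truncated Wald scan
#'
#' Simulates `NS` null statistic vectors under `Psi`, runs the truncated
#' Wald scan on them, estimates the effective test number of every column
#' ([estimate_n_independent()]), Tippett-adjusts the columns, and fits the
#' quantile-coefficient curve of the row minima. The model makes the
#' genome scan's final minima uniform under the null.
#'
#' @param Psi Background-correlation matrix of the (reduced) panel.
#' @param config A [twt_config()].
#' @param NS Number of null simulations (default 1e6; large applications
#'   warrant 1e8, at least 100 times the number of independent variants).
#' @param seed Integer seed.
#' @param chunk Simulation chunk size (memory control).
#' @return Object of class `calibration_model`: list with `Neff`
#'   (length Q+1), `coef_curve`, `minSP` (simulated calibrated null
#'   minima), `ntest_burden`, `coef_burden`, `K`, `NS`.
#' @export
build_calibration <- function(Psi, config = twt_config(), NS = 1e6,
                              seed = 1L, chunk = 1e5) {
  Psi <- nearest_pd(as.matrix(Psi))
  K <- nrow(Psi)
  NS <- as.integer(NS)
  set.seed(seed)
  SP <- matrix(NA_real_, NS, config$Q + 1L)
  done <- 0L
  while (done < NS) {
    nb <- min(chunk, NS - done)
    Ts <- rmvn(nb, Psi)
    SP[done + seq_len(nb), ] <- twt_genome_mat(Ts, p_from_t(Ts), Psi, config)
    done <- done + nb
  }
  Neff <- rep(1, config$Q + 1L)
  # min-p column first: it is the limiting correction for deep threshold
  # columns whose support is too thin to fit
  Neff[config$Q + 1L] <- estimate_n_independent(SP[, config$Q + 1L])
  for (q in seq_len(config$Q)) {
    Neff[q] <- tryCatch(estimate_n_independent(SP[, q]),
                        error = function(e) Neff[config$Q + 1L])
  }
  for (q in seq_len(config$Q + 1L)) {
    SP[, q] <- tippett_adjust(SP[, q], Neff[q])
  }
  minSP <- do.call(pmin, c(asplit(SP, 2L), list(na.rm = TRUE)))
  curve <- fit_quantile_coefficients(minSP)
  ntest_burden <- estimate_n_independent(minSP)
  # tail plateau of the coefficient curve: the residual calibration factor
  # applied to the most significant results
  coef_burden <- exp(curve$log_u[1L] - curve$log_q[1L])
  structure(list(Neff = Neff, coef_curve = curve, minSP = minSP,
                 ntest_burden = ntest_burden, coef_burden = coef_burden,
                 K = K, NS = NS, Q = config$Q),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration model: K = %d, NS = %g, ntest burden = %.2f, coef burden = %.2f\n",
    x$K, x$NS, x$ntest_burden, x$coef_burden))
  invisible(x)
}

#' Calibrated minimum-p combination (MinGWAS)
#'
#' The per-variant minimum of the K single-study p-values, calibrated
#' against its simulated null distribution under `Psi` so the result is
#' uniform under the null (the raw minimum is by definition inflated).
#'
#' @param panel A harmonized [gwas_panel()].
#' @param Psi Background-correlation matrix.
#' @param NS Number of null simulations.
#' @param seed Integer seed.
#' @return Vector of calibrated minimum p-values.
#' @export
mingwas <- function(panel, Psi, NS = 1e6, seed = 1L) {
  minp <- do.call(pmin, asplit(panel$p, 2L))
  Ts <- simulate_null_panel(Psi, NS, seed)
  null_min <- do.call(pmin, asplit(p_from_t(Ts), 2L))
  curve <- fit_quantile_coefficients(null_min)
  apply_calibration(minp, curve)
}

#' Study-wide significance threshold from calibration burdens
#'
#' Converts a conventional genome-wide significance level into the
#' equivalent threshold on a single combined study's raw p-values, by
#' multiplying with the effective-test-number burden and the residual
#' calibration-coefficient burden reported by the pipeline.
#'
#' @param base_alpha Conventional threshold (e.g. `5e-8`).
#' @param ntest_burden Effective-test-number burden.
#' @param coef_burden Calibration-coefficient burden.
#' @return Threshold, reported at 3 significant digits.
#' @export
derive_studywide_threshold <- function(base_alpha, ntest_burden,
                                       coef_burden) {
  stopifnot(base_alpha > 0, ntest_burden > 0, coef_burden > 0)
  signif(base_alpha * ntest_burden * coef_burden, 3)
}
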