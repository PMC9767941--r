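#' Estimate the inflation factor of a GWAS from its T statistics
#'
#' Models the squared T statistics as a two-component mixture: a fraction
#' `1 - p` of variants carry only estimation error plus inflation,
#' `t^2 ~ (1 + I) * chi2_1`, and a fraction `p` additionally carry true
#' effects with variance `Lambda`, `t^2 ~ (1 + I + Lambda) * chi2_1`. The
#' first two moments of `t^2` satisfy
#' `E(t^2) = 1 + I + p * Lambda` and
#' `Var(t^2) = 2 * E(t^2)^2 + 3 * Lambda^2 * p * (1 - p)`,
#' so for any candidate inflation `I` the pair `(Lambda, p)` is determined by
#' the observed moments. `I` itself is found by a golden-section search that
#' matches the lower empirical quantiles of `t^2` (probability levels 0.1 to
#' 0.5, where true-effect contamination is minimal) against the implied
#' mixture distribution. Unlike the genomic-control median ratio, the
#' estimate is not biased upward by polygenic true effects.
#'
#' @param t Numeric vector of T statistics (M variants; a warning is issued
#'   below 1000).
#' @param probs Quantile levels used for the fit.
#' @return An object of class `inflation_fit`: list with `s` (inflation
#'   factor, `s = I + 1`, clamped at 1), `I`, `Lambda`, `p_effect`.
#' @export
estimate_inflation <- function(t, probs = seq(0.1, 0.5, by = 0.1)) {
  t <- t[is.finite(t)]
  M <- length(t)
  if (M < 1000L) warning("estimate_inflation: fewer than 1000 variants")
  x <- t * t
  m1 <- mean(x)
  v <- stats::var(x)
  if (!is.finite(m1) || !is.finite(v)) stop("non-finite moments of t^2")
  q_emp <- stats::quantile(x, probs, names = FALSE, type = 7)

  # (Lambda, p) implied by the two moment equations at a candidate I
  solve_lp <- function(I) {
    cc <- m1 - 1 - I            # = p * Lambda
    if (cc <= 0) return(c(0, 0))
    d <- v - 2 * m1 * m1        # = 3 Lambda^2 p (1-p)
    if (d <= 0) return(c(cc, 1))
    p <- clamp(3 * cc * cc / (d + 3 * cc * cc), 1e-6, 1)
    c(cc / p, p)
  }
  objective <- function(I) {
    lp <- solve_lp(I)
    Lambda <- lp[1]; p <- lp[2]
    Fq <- (1 - p) * stats::pchisq(q_emp / (1 + I), df = 1L) +
      p * stats::pchisq(q_emp / (1 + I + Lambda), df = 1L)
    sum((Fq - probs)^2)
  }
  # The objective is flat along the ridge I + p*Lambda = const whenever the
  # implied mixture degenerates (p -> 1), so the minimizer alone does not
  # identify I. A tiny monotone penalty (scale 1/M, i.e. of the order of
  # the objective's sampling noise) resolves the ambiguity toward the
  # largest I -- inflation is by definition the scale shared by all
  # variants -- while real contamination curvature dwarfs it.
  I_hi <- max(0, m1 - 1)
  if (I_hi < 1e-8) {
    I_hat <- 0
  } else {
    obj_reg <- function(I) objective(I) + (1 - I / I_hi) / M
    grid <- seq(0, I_hi, length.out = 201L)
    obj <- vapply(grid, obj_reg, numeric(1))
    i0 <- which.min(obj)
    step <- I_hi / 200
    I_hat <- stats::optimize(obj_reg,
                             interval = c(max(0, grid[i0] - step),
                                          min(I_hi, grid[i0] + step)),
                             tol = 1e-6)$minimum
  }
  if (!is.finite(I_hat)) {
    warning("inflation fit failed; falling back to genomic control")
    I_hat <- max(0, stats::median(x) / stats::qchisq(0.5, 1L) - 1)
  }
  lp <- solve_lp(I_hat)
  # an "effect" carried by essentially all variants is a shared scale,
  # i.e. inflation by definition; fold it in (resolves the I vs Lambda
  # ridge when p -> 1, where the two are indistinguishable)
  if (lp[2] >= 0.95) {
    I_hat <- I_hat + lp[1] * lp[2]
    lp <- c(0, 0)
  }
  structure(list(s = 1 + I_hat, I = I_hat, Lambda = lp[1], p_effect = lp[2]),
            class = "inflation_fit")
}

#' @export
print.inflation_fit <- function(x, ...) {
  cat(sprintf("inflation fit: s = %.4f (I = %.4f), Lambda = %.3f, p = %.3f\n",
              x$s, x$I, x$Lambda, x$p_effect))
  invisible(x)
}

#' Genomic-control inflation factor (median ratio)
#'
#' The classical comparator: `median(t^2) / qchisq(0.5, 1)`. Biased upward in
#' the presence of polygenic true effects; provided for comparison with
#' [estimate_inflation()].
#'
#' @param t Numeric vector of T statistics.
#' @return Lambda-GC (clamped at 1 from below is NOT applied here).
#' @export
lambda_gc <- function(t) {
  stats::median(t * t, na.rm = TRUE) / stats::qchisq(0.5, df = 1L)
}

#' Divide out an inflation factor from a GWAS table
#'
#' Rescales `t` by `1/sqrt(s)` and `se` by `sqrt(s)` (so `beta` and the
#' identity `t = beta/se` are preserved) and recomputes `p`.
#'
#' @param table A [gwas_table()].
#' @param s Inflation factor, `s >= 1`.
#' @return The adjusted [gwas_table()].
#' @export
adjust_inflation <- function(table, s) {
  if (s < 1) stop("inflation factor s must be >= 1")
  table$t <- table$t / sqrt(s)
  table$se <- table$se * sqrt(s)
  table$p <- p_from_t(table$t)
  table
}

#' Estimate the background correlation between two GWASs
#'
#' The background correlation psi is the correlation of the two studies' T
#' statistics under the null (driven by sample overlap and non-genetic
#' phenotype correlation). Starting from the crude correlation of all
#' statistics, the estimator iteratively restricts to variants that are
#' jointly insignificant under the current estimate -- those whose 2-df
#' quadratic form `(t1,t2) Psi0^-1 (t1,t2)^T` has an upper-tail chi-squared
#' probability above 0.5 -- and recomputes the correlation on that set, until
#' successive estimates differ by at most `eps`. This removes the bias that
#' true (correlated) effects induce in the naive all-variant correlation.
#'
#' @param t1,t2 Numeric vectors of T statistics of equal length (a warning is
#'   issued below 1000).
#' @param eps Convergence tolerance (default `1e-4`).
#' @param max_iter Iteration cap (default 100; the last iterate is returned
#'   with a warning on non-convergence).
#' @return Estimated psi, clamped to `[-0.999, 0.999]`.
#' @export
estimate_psi <- function(t1, t2, eps = 1e-4, max_iter = 100L) {
  stopifnot(length(t1) == length(t2))
  if (length(t1) < 1000L) warning("estimate_psi: fewer than 1000 variants")
  psi <- clamp(stats::cor(t1, t2), -0.999, 0.999)
  cut2 <- stats::qchisq(0.5, df = 2L)  # joint-insignificance cut on the 2-df form
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ct <- (t1 * t1 - 2 * psi * t1 * t2 + t2 * t2) / (1 - psi * psi)
    keep <- ct < cut2
    if (sum(keep) < 100L) {
      warning("estimate_psi: fewer than 100 jointly insignificant variants")
      break
    }
    psi_new <- clamp(stats::cor(t1[keep], t2[keep]), -0.999, 0.999)
    done <- abs(psi_new - psi) <= eps
    psi <- psi_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged && iter == max_iter) {
    warning("estimate_psi did not converge; returning last iterate")
  }
  clamp(psi, -0.999, 0.999)
}

#' Estimate the background-correlation matrix of a panel
#'
#' Applies [estimate_psi()] to every study pair on each subset of
#' approximately unlinked variants (see [sample_unlinked()]) and takes the
#' median across rounds. The result is symmetrized, given a unit diagonal,
#' and repaired to the nearest positive-definite correlation matrix when
#' needed.
#'
#' @param panel A [gwas_panel()] with K >= 2 studies.
#' @param subsets Optional list of variant-index subsets; default is the full
#'   panel in a single round.
#' @return K x K background-correlation matrix Psi.
#' @export
estimate_psi_matrix <- function(panel, subsets = NULL) {
  Tm <- panel$t
  K <- ncol(Tm)
  stopifnot(K >= 2L)
  if (is.null(subsets)) subsets <- list(seq_len(nrow(Tm)))
  Psi <- diag(K)
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      est <- vapply(subsets, function(idx) {
        estimate_psi(Tm[idx, i], Tm[idx, j])
      }, numeric(1))
      Psi[i, j] <- Psi[j, i] <- stats::median(est)
    }
  }
  repaired <- nearest_pd(Psi)
  if (max(abs(repaired - Psi)) > 1e-8) {
    message("estimate_psi_matrix: nearest-PD repair applied")
  }
  repaired
}

#' Estimate the effect-correlation matrix and effect model of a panel
#'
#' Let `Z` be the K x K second-moment matrix of the T statistics
#' (`Z_ij = E(t_i t_j)`). Under the null `Z = Psi`, so the genome-level
#' covariance of true effects on the T scale is `A = Z - Psi`, and on the
#' beta scale `H = A o sigma sigma^T` per variant. Three constructions are
#' supported:
#'
#' * `"all"`: `Z` over all (subset) variants, reference `Psi` -- best under
#'   polygenicity, where all variants share the same effect correlation.
#' * `"sig"`: `Z` over variants significant in the Wald test (p < `L`),
#'   reference `Psi_nosig` computed on the non-significant variants -- aimed
#'   at major-gene architectures; falls back to `"all"` with a warning when
#'   fewer than 100 variants are significant.
#' * `"stb"`: the effect-correlation matrix is fixed at all ones and the
#'   effect vector at `sigma_k * sqrt(Z_kk - 1)` -- a stable choice when the
#'   estimation error of `H` is large.
#'
#' The effect correlation is `Pi_ij = A_ij / sqrt(A_ii A_jj)` (clamped to
#' `[-1, 1]`); studies whose mean chi-squared falls below 1.001 have the
#' corresponding diagonal of `Z` floored at 1.001 so the normalization never
#' divides by ~0. The returned model carries everything needed to build the
#' per-variant combination vector `h = sign(Pi - Psi)_k H` (row `k = 1` by
#' convention).
#'
#' @param panel A [gwas_panel()] (or a list with `t` and `se` matrices).
#' @param Psi Background-correlation matrix from [estimate_psi_matrix()].
#' @param variant One of `"all"`, `"sig"`, `"stb"`.
#' @param L Wald-test significance threshold defining `"sig"` (default
#'   `1e-5`).
#' @param subset Optional variant indices over which `Z` is computed.
#' @return An object of class `effect_model`: list with `Pi`, `Z`, `A`,
#'   `Psi`, `Psi_ref` (`Psi` or `Psi_nosig`), `sign_row`, `hstar` (for
#'   `"stb"`), and `variant`.
#' @export
estimate_effect_model <- function(panel, Psi, variant = c("all", "sig", "stb"),
                                  L = 1e-5, subset = NULL) {
  variant <- match.arg(variant)
  Tm <- panel$t
  if (!is.null(subset)) Tm <- Tm[subset, , drop = FALSE]
  M <- nrow(Tm)
  K <- ncol(Tm)
  Psi_ref <- Psi
  if (variant == "sig") {
    stopifnot(L > 0, L < 1)
    # Wald p < L  <=>  quadratic form above the chi-squared cutoff
    sig <- row_quadform(Tm, Psi) >
      stats::qchisq(L, df = K, lower.tail = FALSE)
    if (sum(sig) < 100L) {
      warning("fewer than 100 Wald-significant variants; falling back to 'all'")
      variant <- "all"
    } else {
      Psi_ref <- crossprod(Tm[!sig, , drop = FALSE]) / sum(!sig)
      Tm <- Tm[sig, , drop = FALSE]
      M <- nrow(Tm)
    }
  }
  Z <- crossprod(Tm) / M
  # floor: studies with mean chi2 < 1.001 would make the Pi normalization
  # blow up; force E(chi2) >= 1.001 relative to the null reference
  A <- Z - Psi_ref
  diag(A) <- pmax(diag(A), 0.001)
  Pi <- A / sqrt(tcrossprod(diag(A)))
  Pi <- clamp(Pi, -1, 1)
  diag(Pi) <- 1
  if (variant == "stb") {
    Pi_out <- matrix(1, K, K)
  } else {
    Pi_out <- Pi
  }
  structure(list(
    variant = variant,
    Z = Z,
    A = A,
    Psi = Psi,
    Psi_ref = Psi_ref,
    Pi = Pi_out,
    sign_row = sign_pos(Pi_out - Psi)[1L, ],
    hstar = sqrt(pmax(diag(Z) - 1, 0.001))
  ), class = "effect_model")
}

# Per-variant vector u = h o e (the EbICoW weighting vector on the T scale),
# given the per-variant standard errors. For "all"/"sig",
# u_m = A^T (sign_row o sigma_m); for "stb", u is the constant hstar; for
# "hom" (homogeneous expected effects, h proportional to the all-ones
# vector) u = 1/sigma, giving the t_C form.
ebicow_u <- function(model, SE) {
  M <- nrow(SE)
  switch(model$variant,
    stb = matrix(model$hstar, M, length(model$hstar), byrow = TRUE),
    hom = 1 / SE,
    sweep(SE, 2L, model$sign_row, `*`) %*% model$A
  )
}

# Homogeneous-effect pseudo-model (h proportional to b): the stable choice
# for forced combinations of near-collinear studies, where any estimated
# asymmetry in h is amplified by Psi^-1 into a pure-noise contrast.
hom_effect_model <- function(K) {
  structure(list(variant = "hom", sign_row = rep(1, K),
                 Pi = matrix(1, K, K)),
            class = "effect_model")
}
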