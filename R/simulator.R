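#' Specification of a summary-statistics simulation scenario
#'
#' Describes a panel of K GWASs over M independent variants: the null T
#' statistics are multivariate normal with background-correlation matrix
#' `Psi`, optional per-study inflation adds `N(0, I_k)`, and the first
#' `floor(p_effect * M)` variants receive a true-effect draw from
#' `N(0, Pi o theta theta^T)`. The implied mean chi-squared of study k is
#' `1 + p_effect * theta_k^2 + I_k`.
#'
#' @param M Number of variants.
#' @param K Number of studies.
#' @param Psi Background-correlation matrix, or a scalar exchangeable psi.
#' @param Pi Effect-correlation matrix, or a scalar exchangeable pi.
#' @param p_effect Proportion of variants with true effects, in `[0, 1]`.
#' @param theta Per-study effect scale (scalar recycled to K); study k's
#'   causal statistics gain variance `theta_k^2`.
#' @param inflate Per-study inflation variance I (scalar recycled to K).
#' @param n_nominal Nominal sample size written into the panel.
#' @param replicates Number of replicates a harness should run.
#' @param alpha Evaluation threshold (default `0.05 / M`).
#' @param seed Integer seed.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(M, K, Psi = 0, Pi = 0, p_effect = 0, theta = 0,
                          inflate = 0, n_nominal = 10000L, replicates = 1L,
                          alpha = 0.05 / M, seed = 1L) {
  if (length(Psi) == 1L) Psi <- exch_corr(K, Psi)
  if (length(Pi) == 1L) Pi <- exch_corr(K, Pi)
  theta <- rep_len(theta, K)
  inflate <- rep_len(inflate, K)
  stopifnot(M >= 1L, K >= 1L, p_effect >= 0, p_effect <= 1,
            all(abs(Psi) <= 1), all(abs(Pi) <= 1), all(inflate >= 0))
  structure(list(M = as.integer(M), K = as.integer(K), Psi = Psi, Pi = Pi,
                 p_effect = p_effect, theta = theta, inflate = inflate,
                 n_nominal = n_nominal, replicates = as.integer(replicates),
                 alpha = alpha, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Expected mean chi-squared of a simulated study
#'
#' `1 + p_effect * theta_k^2` (without inflation): the null contributes
#' mean 1 and a fraction `p_effect` of variants contribute an extra
#' `theta_k^2`.
#'
#' @param p_effect Causal fraction.
#' @param theta_k Effect scale of study k.
#' @return Expected mean chi-squared.
#' @export
expected_mean_chi2 <- function(p_effect, theta_k) {
  stopifnot(p_effect >= 0, p_effect <= 1)
  1 + p_effect * theta_k^2
}

#' Effect scale that yields a target mean chi-squared
#'
#' Inverts [expected_mean_chi2()]: `theta = sqrt((Echi2 - 1) / p_effect)`.
#'
#' @param Echi2 Target mean chi-squared (>= 1).
#' @param p_effect Causal fraction (> 0 unless `Echi2 = 1`).
#' @return Effect scale theta.
#' @export
theta_for_chi2 <- function(Echi2, p_effect) {
  stopifnot(Echi2 >= 1)
  if (Echi2 == 1) return(0)
  sqrt((Echi2 - 1) / p_effect)
}

#' Simulate one replicate of a summary-statistics scenario
#'
#' @param spec A [scenario_spec()].
#' @param seed Seed for this replicate (default `spec$seed`).
#' @return A [gwas_panel()] (`se = 1`, `beta = t`); the logical vector of
#'   causal flags is attached as attribute `"causal"`.
#' @export
simulate_summary_scenario <- function(spec, seed = spec$seed) {
  set.seed(seed)
  M <- spec$M; K <- spec$K
  Tm <- rmvn(M, nearest_pd(spec$Psi))
  for (k in seq_len(K)) {
    if (spec$inflate[k] > 0) {
      Tm[, k] <- Tm[, k] + stats::rnorm(M, 0, sqrt(spec$inflate[k]))
    }
  }
  Mc <- floor(spec$p_effect * M)
  causal <- rep(FALSE, M)
  if (Mc >= 1L) {
    causal[seq_len(Mc)] <- TRUE
    Sig_eff <- spec$Pi * tcrossprod(spec$theta)
    ev <- eigen(Sig_eff, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      warning("effect covariance Pi o theta theta^T not PSD; repaired")
      e <- eigen(Sig_eff, symmetric = TRUE)
      Sig_eff <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    }
    if (any(diag(Sig_eff) > 0)) {
      e <- eigen(Sig_eff, symmetric = TRUE)
      Lhalf <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
      Tm[seq_len(Mc), ] <- Tm[seq_len(Mc), ] +
        matrix(stats::rnorm(Mc * K), Mc, K) %*% Lhalf
    }
  }
  v <- data.frame(variant_id = paste0("snp", seq_len(M)),
                  chrom = "1", pos = seq_len(M),
                  effect_allele = "A", other_allele = "G",
                  stringsAsFactors = FALSE)
  ones <- matrix(1, M, K)
  panel <- gwas_panel(v, beta = Tm, se = ones,
                      n = matrix(spec$n_nominal, M, K),
                      t = Tm, p = p_from_t(Tm))
  attr(panel, "causal") <- causal
  panel
}

#' Specification of the overlapping-cohort individual-level generator
#'
#' Synthetic genotypes (independent variants, allele frequencies uniform
#' on 0.05-0.5) and a quantitative phenotype in which a fraction `h2` of
#' the variance is explained by a fraction `causal_frac` of the variants.
#' Three cohorts are drawn from the `n_individuals` according to
#' `overlap_pattern`; under full overlap the per-cohort GWASs coincide,
#' under no overlap their background correlation is ~0 (the theoretical
#' background correlation of two cohorts is `Nc / sqrt(N1 N2) * rho`,
#' with `Nc` the shared sample size and `rho` the residual phenotype
#' correlation).
#'
#' @param n_individuals Total sample size (default 2000).
#' @param m_snps Number of variants (default 20000).
#' @param causal_frac Fraction of causal variants (default 0.01).
#' @param h2 Fraction of phenotypic variance explained by the genetic
#'   values (default 0.10).
#' @param cohort_sizes Optional three cohort sizes; defaults depend on
#'   `overlap_pattern` (20/30/50% of n for `"none"`, 50/70/80% for
#'   `"partial"`, 99.5% each for `"full"`).
#' @param overlap_pattern One of `"none"`, `"partial"`, `"full"`.
#' @param seed Integer seed.
#' @return A list of class `overlap_spec`.
#' @export
overlap_spec <- function(n_individuals = 2000L, m_snps = 20000L,
                         causal_frac = 0.01, h2 = 0.10,
                         cohort_sizes = NULL,
                         overlap_pattern = c("none", "partial", "full"),
                         seed = 1L) {
  overlap_pattern <- match.arg(overlap_pattern)
  n <- as.integer(n_individuals)
  if (is.null(cohort_sizes)) {
    cohort_sizes <- switch(overlap_pattern,
      none = round(n * c(0.2, 0.3, 0.5)),
      partial = round(n * c(0.5, 0.7, 0.8)),
      full = rep(round(n * 0.995), 3L))
  }
  stopifnot(h2 > 0, h2 < 1, causal_frac > 0, causal_frac <= 1,
            all(cohort_sizes <= n))
  structure(list(n_individuals = n, m_snps = as.integer(m_snps),
                 causal_frac = causal_frac, h2 = h2,
                 cohort_sizes = as.integer(cohort_sizes),
                 overlap_pattern = overlap_pattern, seed = as.integer(seed)),
            class = "overlap_spec")
}

#' Simulate three overlapping-cohort GWASs and the union GWAS
#'
#' @param spec An [overlap_spec()].
#' @return List with `cohorts` (list of three [gwas_table()]s), `union`
#'   (the union-sample [gwas_table()]), `truth` (causal indices, true
#'   effects, realized genetic-variance fraction), and `cohort_rows`.
#' @export
simulate_overlap_cohorts <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_individuals; m <- spec$m_snps
  f <- stats::runif(m, 0.05, 0.5)
  X <- matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), n, m)
  n_causal <- max(1L, round(spec$causal_frac * m))
  causal <- sort(sample.int(m, n_causal))
  b <- stats::rnorm(n_causal)
  g <- drop(X[, causal, drop = FALSE] %*% b)
  g <- g * sqrt(spec$h2 / stats::var(g))
  y <- g + stats::rnorm(n, 0, sqrt(1 - spec$h2))

  if (spec$overlap_pattern == "none") {
    sizes <- spec$cohort_sizes
    stopifnot(sum(sizes) <= n)
    perm <- sample.int(n)
    stops <- cumsum(sizes)
    rows <- list(perm[seq_len(stops[1])],
                 perm[seq.int(stops[1] + 1L, stops[2])],
                 perm[seq.int(stops[2] + 1L, stops[3])])
  } else {
    rows <- lapply(spec$cohort_sizes, function(sz) sort(sample.int(n, sz)))
  }

  gwas_of <- function(idx, label) {
    Xi <- X[idx, , drop = FALSE]
    yi <- y[idx]
    ni <- length(idx)
    xbar <- colMeans(Xi)
    sxx <- colSums(Xi * Xi) - ni * xbar * xbar
    sxy <- drop(crossprod(Xi, yi)) - ni * xbar * mean(yi)
    syy <- sum((yi - mean(yi))^2)
    ok <- sxx > 1e-8
    slope <- sxy[ok] / sxx[ok]
    sse <- pmax(syy - slope * sxy[ok], 0)
    se <- sqrt(sse / (ni - 2) / sxx[ok])
    gwas_table(paste0("snp", which(ok)), "A", "G",
               beta = slope, se = se, n = ni,
               chrom = "1", pos = which(ok))
  }
  cohorts <- lapply(seq_len(3L), function(i) gwas_of(rows[[i]], i))
  union_rows <- sort(unique(unlist(rows)))
  list(cohorts = cohorts,
       union = gwas_of(union_rows, "union"),
       truth = list(causal = causal, b = b,
                    genetic_variance_fraction = stats::var(g) / stats::var(y)),
       cohort_rows = rows)
}

#' Power and type-I-error study over a simulation scenario
#'
#' Runs `spec$replicates` replicates of [simulate_summary_scenario()] and,
#' for each requested method, records the per-variant power (fraction of
#' causal variants detected at `spec$alpha`) and the empirical per-variant
#' type-I error on the null stratum. Methods whose raw statistic is not
#' uniform under the null (truncated Wald scan, minimum p) are calibrated
#' against a simulated null under the true `Psi` (shared across
#' replicates), so all methods are compared at the same alpha.
#'
#' @param spec A [scenario_spec()] with `p_effect > 0` for power.
#' @param methods Subset of `c("ebicow", "wald", "twt", "mingwas")`.
#' @param NS Null-simulation size for the calibrated methods.
#' @param use_true_psi Use the scenario's `Psi` rather than re-estimating
#'   it in every replicate (default `TRUE`).
#' @return Data.frame with one row per method: `power`, `alpha_emp`
#'   (null-stratum rate at `spec$alpha`), `replicates`.
#' @export
run_power_study <- function(spec,
                            methods = c("ebicow", "wald", "twt", "mingwas"),
                            NS = 1e6, use_true_psi = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  Psi <- nearest_pd(spec$Psi)
  K <- spec$K
  config <- twt_config()
  cal <- NULL
  min_curve <- NULL
  if (any(methods %in% c("twt", "mingwas"))) {
    cal <- build_calibration(Psi, config, NS = NS, seed = spec$seed)
    Ts <- simulate_null_panel(Psi, NS, seed = spec$seed + 1L)
    min_curve <- fit_quantile_coefficients(
      do.call(pmin, asplit(p_from_t(Ts), 2L)))
  }
  hits <- matrix(0, length(methods), 2,
                 dimnames = list(methods, c("causal", "null")))
  totals <- c(causal = 0, null = 0)
  for (rep_i in seq_len(spec$replicates)) {
    panel <- simulate_summary_scenario(spec, seed = spec$seed + rep_i)
    causal <- attr(panel, "causal")
    totals <- totals + c(sum(causal), sum(!causal))
    Psi_use <- if (use_true_psi) Psi else estimate_psi_matrix(panel)
    pv <- list()
    if ("ebicow" %in% methods) {
      em <- estimate_effect_model(panel, Psi_use, "all")
      cmb <- combine_pair_mat(panel$t, panel$se, panel$beta, Psi_use, em)
      pv$ebicow <- cmb$p
    }
    if ("wald" %in% methods) {
      pv$wald <- chisq_sf(row_quadform(panel$t, Psi_use), df = K)
    }
    if ("twt" %in% methods) {
      CP <- twt_genome(panel, Psi_use, config)
      for (q in seq_len(config$Q + 1L)) {
        CP[, q] <- tippett_adjust(CP[, q], cal$Neff[q])
      }
      minCP <- do.call(pmin, c(asplit(CP, 2L), list(na.rm = TRUE)))
      pv$twt <- apply_calibration(minCP, cal$coef_curve)
    }
    if ("mingwas" %in% methods) {
      minp <- do.call(pmin, asplit(panel$p, 2L))
      pv$mingwas <- apply_calibration(minp, min_curve)
    }
    for (m in methods) {
      hits[m, "causal"] <- hits[m, "causal"] + sum(pv[[m]][causal] <= spec$alpha)
      hits[m, "null"] <- hits[m, "null"] + sum(pv[[m]][!causal] <= spec$alpha)
    }
  }
  data.frame(method = methods,
             power = hits[, "causal"] / max(totals["causal"], 1),
             alpha_emp = hits[, "null"] / max(totals["null"], 1),
             replicates = spec$replicates,
             row.names = NULL)
}
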