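#' Configuration of the combination pipeline
#'
#' @param F Minimum `|pi - psi|` worth an EbICoW combination (default 0.05).
#' @param force_psi2 Forced-combination threshold on `psi^2` (default 0.5).
#' @param twt A [twt_config()].
#' @param NS Number of null simulations for calibration (default 1e6; a
#'   message recommends at least 100 x the number of independent variants
#'   for production use).
#' @param seed Integer seed driving every stochastic step.
#' @param min_frac Sample-size filter fraction (applied only when the
#'   panel's `n` is filled in; see [filter_by_sample_size()]).
#' @param L Wald threshold of the `"sig"` effect model.
#' @param Psi Optional known background-correlation matrix (skips
#'   estimation).
#' @param s Optional known vector of inflation factors (skips estimation;
#'   use `rep(1, K)` for no adjustment).
#' @param unlinked Optional list of variant subsets for the estimators
#'   (default: full panel).
#' @param calibration Optional precomputed [build_calibration()] model; it
#'   is reused when its dimensions match the reduced panel, otherwise a
#'   fresh model is built.
#' @param mingwas Also compute the calibrated minimum-p comparator
#'   (default `FALSE`).
#' @return A list of class `cgwas_config`.
#' @export
cgwas_config <- function(F = 0.05, force_psi2 = 0.5, twt = twt_config(),
                         NS = 1e6, seed = 1L, min_frac = 0.6, L = 1e-5,
                         Psi = NULL, s = NULL, unlinked = NULL,
                         calibration = NULL, mingwas = FALSE) {
  stopifnot(F >= 0, force_psi2 > 0, NS >= 1e4, min_frac > 0, min_frac <= 1,
            L > 0, L < 1)
  structure(list(F = F, force_psi2 = force_psi2, twt = twt, NS = NS,
                 seed = as.integer(seed), min_frac = min_frac, L = L,
                 Psi = Psi, s = s, unlinked = unlinked,
                 calibration = calibration, mingwas = mingwas),
            class = "cgwas_config")
}

#' Combine a panel of correlated GWASs into one p-value vector
#'
#' Full pipeline: per-study inflation estimation and adjustment
#' ([estimate_inflation()]), background-correlation estimation
#' ([estimate_psi_matrix()]), iterative pairwise EbICoW
#' ([iterative_ebicow()]), a truncated Wald scan of the reduced panel
#' ([twt_genome()]), column-wise Tippett adjustment with empirically
#' estimated effective test numbers, and quantile-coefficient calibration
#' of the row minima against the simulated null ([build_calibration()]).
#' The background correlations of the reduced panel are obtained in closed
#' form from the stored combination coefficients, so the null simulation
#' replays exactly the combinations applied to the data. The result is a
#' single vector of combined p-values that is uniform under the null and
#' directly comparable with any standard GWAS.
#'
#' @param panel A harmonized [gwas_panel()].
#' @param config A [cgwas_config()].
#' @return Object of class `cgwas_result`: list with `p` (final combined
#'   p-values), `chosen_q` (winning scan column per variant),
#'   `p_mingwas` (when requested), and `report` (inflation fits, `Psi`,
#'   iteration log, `Neff`, burdens, the study-wide threshold at 5e-8, and
#'   the calibration model).
#' @export
cgwas_pipeline <- function(panel, config = cgwas_config()) {
  K <- panel_k(panel)
  M <- panel_m(panel)
  seed <- config$seed

  # 1. inflation
  s <- config$s
  if (is.null(s)) {
    s <- vapply(seq_len(K), function(k) {
      idx <- if (is.null(config$unlinked)) seq_len(M) else
        sort(unique(unlist(config$unlinked)))
      estimate_inflation(panel$t[idx, k])$s
    }, numeric(1))
  }
  stopifnot(all(s >= 1))
  adj <- sqrt(s)
  panel$t <- sweep(panel$t, 2L, adj, `/`)
  panel$se <- sweep(panel$se, 2L, adj, `*`)
  panel$p <- p_from_t(panel$t)

  # 2. background correlation
  Psi <- config$Psi
  if (is.null(Psi) && K >= 2L) {
    Psi <- estimate_psi_matrix(panel, subsets = config$unlinked)
  } else if (K == 1L) {
    Psi <- diag(1)
  }

  # 3. iterative EbICoW
  if (K >= 2L) {
    ie <- iterative_ebicow(panel, F = config$F,
                           force_psi2 = config$force_psi2, Psi = Psi,
                           L = config$L)
    reduced <- ie$panel
    state <- ie$state
  } else {
    reduced <- panel
    state <- structure(list(U = 0L, Psi = Psi, Psi0 = Psi, coef = diag(1),
                            log = data.frame()), class = "iebicow_state")
  }
  Psi_red <- state$Psi

  # 4. truncated Wald scan
  CP <- twt_genome(reduced, Psi_red, config$twt)

  # 5. calibration (reuse a supplied model only if it matches the reduction)
  cal <- config$calibration
  if (is.null(cal) || cal$K != ncol(reduced$t) || cal$Q != config$twt$Q) {
    if (config$NS < 100 * M) {
      message("NS = ", config$NS, " is below 100 x M; tail quantiles below ",
              signif(10 / config$NS, 2), " are extrapolated")
    }
    cal <- build_calibration(Psi_red, config$twt, NS = config$NS,
                             seed = seed + 1L)
  }
  for (q in seq_len(config$twt$Q + 1L)) {
    CP[, q] <- tippett_adjust(CP[, q], cal$Neff[q])
  }
  chosen_q <- apply(CP, 1L, which.min)
  minCP <- do.call(pmin, c(asplit(CP, 2L), list(na.rm = TRUE)))
  p_final <- apply_calibration(minCP, cal$coef_curve)

  p_min_cal <- NULL
  if (isTRUE(config$mingwas)) {
    p_min_cal <- mingwas(panel, Psi, NS = config$NS, seed = seed + 2L)
  }

  report <- list(
    s = s, Psi = Psi, Psi_reduced = Psi_red, U = state$U,
    labels_out = reduced$labels, iteration_log = state$log,
    coef_matrix = state$coef, Neff = cal$Neff,
    ntest_burden = cal$ntest_burden, coef_burden = cal$coef_burden,
    studywide_threshold = derive_studywide_threshold(
      5e-8, cal$ntest_burden, cal$coef_burden),
    calibration = cal
  )
  structure(list(p = p_final, chosen_q = chosen_q, p_mingwas = p_min_cal,
                 variants = panel$variants, report = report),
            class = "cgwas_result")
}

#' @export
print.cgwas_result <- function(x, ...) {
  cat(sprintf(
    "combined GWAS: %d variants, %d studies out (%d combinations), min p = %.3g\n",
    length(x$p), length(x$report$labels_out), x$report$U, min(x$p)))
  cat(sprintf("study-wide threshold at 5e-8: %.3g\n",
              x$report$studywide_threshold))
  invisible(x)
}
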