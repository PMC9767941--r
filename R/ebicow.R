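#' Effect-based inverse covariance weighted combination of one variant
#'
#' Combines the K T statistics of a single variant into one statistic
#' `t_E = (h o e) Psi^-1 t / sqrt((h o e) Psi^-1 (h o e)^T)`, where
#' `e = 1/sigma` and `h` is the effect vector. Under the null (`beta = 0`
#' in every study) `t_E` is asymptotically standard normal regardless of
#' `h`; `h` only moves power. The combined effect is `beta_c = w^T beta`
#' with the weight `w = h C^-1 / (h C^-1 sign_k^T)` (`C = Psi o sigma
#' sigma^T`), normalized so that `w^T sign_k = 1`, and
#' `se_c = sqrt(w^T C w)`, so that `t_E = beta_c / se_c`.
#'
#' Special cases: with `Psi = I` and `h` proportional to the all-ones
#' vector the statistic reduces to classical inverse-variance-weighted
#' meta-analysis; with general `Psi` and constant `h` it reduces to the
#' homogeneous-effect statistic whose square is the 1-df chi-squared
#' S_Hom.
#'
#' @param t K-vector of T statistics.
#' @param sigma K-vector of standard errors (> 0).
#' @param Psi K x K background-correlation matrix (invertible).
#' @param h K-vector effect vector (any non-zero scaling).
#' @param sign_k Optional K-vector of +/-1 giving the direction row
#'   `sign(Pi - Psi)_k`; defaults to all ones.
#' @return List with `t_E`, `beta_c`, `se_c`.
#' @export
ebicow_statistic <- function(t, sigma, Psi, h, sign_k = rep(1, length(t))) {
  stopifnot(length(t) == length(sigma), length(t) == length(h),
            all(sigma > 0))
  Pinv <- tryCatch(solve(Psi), error = function(e) {
    stop("singular background-correlation matrix")
  })
  e <- 1 / sigma
  u <- h * e
  uP <- drop(u %*% Pinv)
  num <- sum(uP * t)
  den2 <- sum(uP * u)
  if (den2 <= 0) stop("degenerate combination (h o e = 0)")
  denom <- sum(uP * e * sign_k)   # h C^-1 sign_k^T
  if (abs(denom) < 1e-300) denom <- sign_pos(denom) * 1e-300
  beta_c <- num / denom
  se_c <- sqrt(den2) / abs(denom)
  list(t_E = beta_c / se_c, beta_c = beta_c, se_c = se_c)
}

# Column-wise scaling without sweep()'s overhead.
colmul <- function(A, v) A * rep(v, each = nrow(A))

# Vectorized pairwise EbICoW on matrices: Tmat/SEmat/Bmat are M x 2 for one
# pair of studies, model is an effect_model fitted on that pair. Returns
# per-variant beta_c, se_c, t_E (and p unless `compute_p = FALSE`; the
# iterative loop compares statistics against quantile cutoffs instead of
# materializing p-values for every candidate), plus the representative
# linear coefficient vector on the T scale (for background-correlation
# updates).
combine_pair_mat <- function(Tmat, SEmat, Bmat, Psi_pair, model,
                             compute_p = TRUE, compute_coef = TRUE) {
  Pinv <- solve(Psi_pair)
  u <- ebicow_u(model, SEmat)
  uP <- u %*% Pinv
  num <- rowSums(uP * Tmat)
  den2 <- rowSums(uP * u)
  den2[den2 < 1e-300] <- 1e-300
  denom <- rowSums(colmul(uP / SEmat, model$sign_row))
  denom[abs(denom) < 1e-300] <- 1e-300
  beta_c <- num / denom
  se_c <- sqrt(den2) / abs(denom)
  t_E <- beta_c / se_c
  list(beta = beta_c, se = se_c, t = t_E,
       p = if (compute_p) p_from_t(t_E) else NULL,
       coef = if (compute_coef) rep_coef(model, Psi_pair, SEmat) else NULL)
}

# Representative combination coefficients on the T scale (median-sigma
# weights), normalized to unit null variance: t_E ~= coef %*% t for a
# typical variant. Exact when standard errors are constant per study.
rep_coef <- function(model, Psi_pair, SEmat) {
  se_rep <- vapply(seq_len(ncol(SEmat)),
                   function(k) stats::median(SEmat[, k]), numeric(1))
  u_rep <- switch(model$variant,
    stb = model$hstar,
    hom = 1 / se_rep,
    drop(crossprod(model$A, model$sign_row * se_rep)))
  coef <- drop(solve(Psi_pair, u_rep))
  coef / sqrt(max(sum(coef * drop(Psi_pair %*% coef)), 1e-300))
}

#' Combine two aligned GWAS tables with EbICoW
#'
#' Produces a new [gwas_table()] whose per-variant statistics are the
#' EbICoW combination of the two inputs. Under the null the combined `t`
#' column is standard normal. The combined sample size is bookkeeping
#' only: the effective `1/se_c^2`, rescaled so its median matches the
#' median pairwise minimum of the input sample sizes.
#'
#' @param g_i,g_j Two [gwas_table()]s over the same variants in the same
#'   order (use [harmonize_panel()] first).
#' @param Psi_pair 2 x 2 background-correlation matrix of the pair.
#' @param Pi_pair 2 x 2 effect-correlation matrix (used for the direction
#'   row `sign(Pi - Psi)`); ignored when `effect_model` is supplied.
#' @param effect_model Optional `effect_model` for the pair (from
#'   [estimate_effect_model()]); fitted with variant `"all"` when absent.
#' @return A [gwas_table()] of the combined study.
#' @export
combine_pair <- function(g_i, g_j, Psi_pair, Pi_pair = NULL,
                         effect_model = NULL) {
  stopifnot(identical(g_i$variant_id, g_j$variant_id))
  Tmat <- cbind(g_i$t, g_j$t)
  SEmat <- cbind(g_i$se, g_j$se)
  Bmat <- cbind(g_i$beta, g_j$beta)
  if (is.null(effect_model)) {
    effect_model <- estimate_effect_model(list(t = Tmat, se = SEmat),
                                          Psi_pair, "all")
    if (!is.null(Pi_pair)) {
      effect_model$sign_row <- sign_pos(Pi_pair - Psi_pair)[1L, ]
    }
  }
  cmb <- combine_pair_mat(Tmat, SEmat, Bmat, Psi_pair, effect_model)
  n_c <- combined_n(cmb$se, g_i$n, g_j$n)
  gwas_table(g_i$variant_id, g_i$effect_allele, g_i$other_allele,
             beta = cmb$beta, se = cmb$se, n = n_c, t = cmb$t, p = cmb$p,
             chrom = g_i$chrom, pos = g_i$pos)
}

combined_n <- function(se_c, n_i, n_j) {
  n_min <- pmin(n_i, n_j)
  if (all(is.na(n_min))) return(rep(NA_real_, length(se_c)))
  eff <- 1 / (se_c * se_c)
  round(eff * stats::median(n_min, na.rm = TRUE) / stats::median(eff))
}

# Calibration sanity check on a combined statistic: the mean of t_E^2 over
# the non-significant stratum (two-sided p >= p0) must match the truncated
# 1-df chi-squared mean. Robust to a minority of true effects because the
# large statistics are excluded; catches a mis-scaled null.
null_stratum_ratio <- function(t_E, p0 = 0.01) {
  q <- stats::qchisq(1 - p0, df = 1L)
  x <- t_E * t_E
  x <- x[x <= q]
  if (length(x) < 100L) return(NA_real_)
  mean(x) / chi2_1_trunc_mean(q)
}

# Null-calibration sanity of a combined statistic. The cheap truncated-mean
# ratio accepts immediately when within band; otherwise (either genuine
# miscalibration or sub-threshold true signal leaking into the stratum) the
# decision escalates to the mixture-model inflation estimate, which
# separates a causal minority from a mis-scaled null.
calibration_ok <- function(t_E, band = c(0.95, 1.05)) {
  r <- null_stratum_ratio(t_E)
  if (!is.finite(r)) return(FALSE)
  if (r >= band[1] && r <= band[2]) return(TRUE)
  s <- suppressWarnings(estimate_inflation(t_E)$s)
  is.finite(s) && s >= band[1] && s <= band[2]
}

#' Choose the best of the three EbICoW candidates for one pair
#'
#' Builds the three candidate combinations of a pair of studies -- effect
#' model `"all"` (polygenic), `"sig"` (major-gene) and `"stb"` (stable,
#' all-ones effect correlation) -- and returns the one maximizing a power
#' proxy: the number of variants with combined p below `proxy_alpha`,
#' among candidates whose null-stratum variance check passes. Ties prefer
#' `"all"`, then `"sig"`, then `"stb"`. If no candidate passes the check,
#' the proxy winner is returned flagged `ok = FALSE` (rejected upstream).
#'
#' @param Tmat,SEmat,Bmat M x 2 matrices of the pair's statistics.
#' @param Psi_pair 2 x 2 background-correlation matrix.
#' @param L Wald threshold defining the `"sig"` stratum.
#' @param proxy_alpha Power-proxy threshold (default `1e-5`).
#' @param compute_p Also materialize the per-variant p-values (the internal
#'   iterative loop defers this until a combination is accepted).
#' @return List with the winning combination (`beta`, `se`, `t`, `p`,
#'   `coef`), the chosen `variant`, `ok`, and the pair effect correlation
#'   `Pi` of the winner.
#' @export
optimize_pair <- function(Tmat, SEmat, Bmat, Psi_pair, L = 1e-5,
                          proxy_alpha = 1e-5, compute_p = TRUE) {
  pair <- list(t = Tmat, se = SEmat)
  variants <- c("all", "sig", "stb")
  cut1 <- stats::qchisq(proxy_alpha, df = 1L, lower.tail = FALSE)
  cands <- vector("list", 3L)
  ok <- counts <- numeric(3L)
  for (v in seq_along(variants)) {
    model <- suppressWarnings(
      estimate_effect_model(pair, Psi_pair, variants[v], L = L))
    if (variants[v] == "sig" && model$variant == "all") {
      # too few significant variants: the fallback model equals the "all"
      # candidate already built
      cands[[v]] <- cands[[1L]]
      ok[v] <- ok[1L]; counts[v] <- counts[1L]
      next
    }
    cands[[v]] <- combine_pair_mat(Tmat, SEmat, Bmat, Psi_pair, model,
                                   compute_p = FALSE, compute_coef = FALSE)
    cands[[v]]$model <- model
    ok[v] <- calibration_ok(cands[[v]]$t)
    counts[v] <- sum(cands[[v]]$t^2 >= cut1)
  }
  pool <- if (any(ok == 1)) which(ok == 1) else seq_len(3L)
  best <- pool[which.max(counts[pool])]  # which.max keeps stability order
  out <- cands[[best]]
  out$coef <- rep_coef(out$model, Psi_pair, SEmat)
  if (compute_p) out$p <- p_from_t(out$t)
  out$variant <- variants[best]
  out$ok <- any(ok == 1)
  out$Pi <- out$model$Pi
  out
}

# Cutoff-based version of evaluate_combination: identical decision, but
# compares statistics against chi-squared quantiles instead of computing
# per-variant p-values (the hot path of the iterative loop). Ti2 holds the
# squared statistics of the two inputs: a combination must also improve on
# each input alone, otherwise one that merely reproduces its stronger input
# (near-zero weight on the other) would pass.
evaluate_fast <- function(t_E, wald2, Ti2, probes = 10^(-(3:6)),
                          npairs = 1) {
  cut_E <- stats::qchisq(probes, df = 1L, lower.tail = FALSE)
  cut_W <- stats::qchisq(probes, df = 2L, lower.tail = FALSE)
  # p_min Tippett-adjusted (N = 2) below a  <=>  max(t1^2, t2^2) above cut
  cut_M <- stats::qchisq(-expm1(0.5 * log1p(-probes)), df = 1L,
                         lower.tail = FALSE)
  tE2 <- t_E * t_E
  tmax2 <- pmax(Ti2[, 1L], Ti2[, 2L])
  n_E <- vapply(cut_E, function(cc) sum(tE2 >= cc), numeric(1))
  n_W <- vapply(cut_W, function(cc) sum(wald2 >= cc), numeric(1))
  n_M <- vapply(cut_M, function(cc) sum(tmax2 >= cc), numeric(1))
  n_I <- vapply(cut_E, function(cc) {
    max(sum(Ti2[, 1L] >= cc), sum(Ti2[, 2L] >= cc))
  }, numeric(1))
  n_best <- pmax(n_W, n_M, n_I)
  dominance_ok(n_E, n_best, npairs) && calibration_ok(t_E)
}

# Dominance with a noise-robust margin: the combination must match every
# comparator at every probe, and its aggregate excess over the probe grid
# must clear a Poisson-scale z margin. The margin is set for a ~1%
# familywise false-acceptance rate per panel: the iterative loop tries up
# to `npairs` pairs and three candidate effect models each, and a
# data-adapted combination direction beats sparse tail counts by chance
# more easily than the Poisson scale suggests.
dominance_ok <- function(n_E, n_best, npairs = 1) {
  if (any(n_E < n_best)) return(FALSE)
  z <- stats::qnorm(1 - 0.01 / (3 * max(npairs, 1)))
  sum(n_E - n_best) > z * sqrt(max(sum(n_best), 1))
}

#' Accept or reject an EbICoW combination
#'
#' The combined study is accepted when it dominates both comparators on a
#' threshold grid and is calibrated. At each probe threshold in
#' `10^-3 ... 10^-6`, the count of variants with combined p below the
#' threshold must be at least the count for the pair Wald test, for the
#' pair minimum p-value (Tippett-normalized with N = 2 to the same alpha
#' scale), and -- when the input p-values are supplied -- for each input
#' study alone (a combination that merely reproduces its stronger input
#' brings no pairwise gain); the aggregate excess over the probe grid must
#' additionally clear a Poisson-scale z margin whose critical value grows
#' with the number of pairs being screened (`npairs`), so that chance
#' fluctuations of a data-adapted combination direction do not trigger
#' spurious combinations anywhere in the panel (the margin targets a ~1%
#' familywise false-acceptance rate). Finally the combined statistic must
#' pass the
#' null-calibration check: the mean of `t_E^2` over the non-significant
#' stratum within `[0.95, 1.05]` of its truncated chi-squared expectation,
#' escalating to the mixture-model inflation estimate when sub-threshold
#' signal inflates the stratum.
#'
#' @param g_E Combined result: list with elements `t` and `p` (or a
#'   [gwas_table()]).
#' @param p_wald Per-variant Wald p-values of the pair.
#' @param p_min Per-variant minimum of the pair's p-values.
#' @param probes Probe thresholds.
#' @param p_inputs Optional M x 2 matrix of the two input studies'
#'   p-values (enables the per-input dominance requirement).
#' @param npairs Number of candidate pairs the caller is screening (sets
#'   the familywise margin; the iterative loop passes K*(K-1)/2).
#' @return `TRUE` to accept the combination.
#' @export
evaluate_combination <- function(g_E, p_wald, p_min,
                                 probes = 10^(-(3:6)), p_inputs = NULL,
                                 npairs = 1) {
  p_E <- g_E$p
  p_min_adj <- tippett_adjust(p_min, 2)
  n_E <- vapply(probes, function(a) sum(p_E <= a), numeric(1))
  n_W <- vapply(probes, function(a) sum(p_wald <= a), numeric(1))
  n_M <- vapply(probes, function(a) sum(p_min_adj <= a), numeric(1))
  n_best <- pmax(n_W, n_M)
  if (!is.null(p_inputs)) {
    n_I <- vapply(probes, function(a) {
      max(colSums(p_inputs <= a))
    }, numeric(1))
    n_best <- pmax(n_best, n_I)
  }
  dominance_ok(n_E, n_best, npairs) && calibration_ok(g_E$t)
}

#' Iterative pairwise EbICoW over a panel
#'
#' Repeatedly combines the pair of studies with the largest entry of
#' `D = |Pi - Psi|` (ties broken by the lexicographically smallest index
#' pair): the pair is combined by [optimize_pair()], and the result is
#' kept if [evaluate_combination()] accepts it, in which case the pair is
#' replaced by the combined study, the background and effect correlations
#' are updated, and the accepted-combination count `U` is incremented;
#' otherwise that entry of `D` is zeroed. Pairs whose squared background
#' correlation exceeds `force_psi2` are combined up front regardless of
#' the evaluation (near-collinear studies make `Psi` ill-conditioned).
#' The loop ends when every live entry of `D` is at most `F`.
#'
#' The background correlations of a combined study with the remaining ones
#' are updated in closed form from the representative combination
#' coefficients (a combined T statistic is a linear map of the input T
#' statistics), so `Psi` stays exact given the initial estimate; the
#' cumulative coefficient matrix mapping original studies to the output
#' panel is returned for null replay.
#'
#' @param panel A harmonized, inflation-adjusted [gwas_panel()].
#' @param F Minimum `|pi - psi|` worth combining (default 0.05).
#' @param force_psi2 Forced-combination threshold on `psi^2` (default 0.5).
#' @param Psi Optional known background-correlation matrix; estimated with
#'   [estimate_psi_matrix()] when absent.
#' @param L Wald threshold for the `"sig"` effect model.
#' @return List with `panel` (the reduced [gwas_panel()]) and `state`
#'   (class `iebicow_state`): `U`, `Psi` (reduced), `Psi0` (input), `coef`
#'   (K_out x K_in coefficient matrix), `D`, and a log data.frame with one
#'   row per iteration.
#' @export
iterative_ebicow <- function(panel, F = 0.05, force_psi2 = 0.5, Psi = NULL,
                             L = 1e-5) {
  Tm <- panel$t; SE <- panel$se; B <- panel$beta; N <- panel$n
  labels <- panel$labels
  K0 <- ncol(Tm)
  if (is.null(Psi)) Psi <- estimate_psi_matrix(panel)
  Psi_cur <- Psi
  Acum <- diag(K0)
  U <- 0L
  log_rows <- list()

  combine_at <- function(i, j) {
    optimize_pair(Tm[, c(i, j)], SE[, c(i, j)], B[, c(i, j)],
                  Psi_cur[c(i, j), c(i, j)], L = L, compute_p = FALSE)
  }
  apply_combination <- function(i, j, cand) {
    coef <- cand$coef
    # implied background correlation of the combined statistic with the rest
    psi_new <- drop(coef %*% Psi_cur[c(i, j), , drop = FALSE])
    keep <- setdiff(seq_len(ncol(Tm)), c(i, j))
    Psi_next <- rbind(cbind(Psi_cur[keep, keep, drop = FALSE],
                            psi_new[keep]),
                      c(psi_new[keep], 1))
    n_c <- combined_n(cand$se, N[, i], N[, j])
    Tm <<- cbind(Tm[, keep, drop = FALSE], cand$t)
    SE <<- cbind(SE[, keep, drop = FALSE], cand$se)
    B <<- cbind(B[, keep, drop = FALSE], cand$beta)
    N <<- cbind(N[, keep, drop = FALSE], n_c)
    Acum <<- rbind(Acum[keep, , drop = FALSE],
                   coef[1] * Acum[i, ] + coef[2] * Acum[j, ])
    labels <<- c(labels[keep], paste0(labels[i], "+", labels[j]))
    Psi_cur <<- nearest_pd(clamp(Psi_next, -0.999, 0.999))
  }

  repeat {
    K <- ncol(Tm)
    if (K < 2L) break
    # forced combinations first: near-collinear pairs destabilize Psi^-1
    off <- Psi_cur; diag(off) <- 0
    if (max(off^2) > force_psi2) {
      ij <- which(off^2 == max(off^2), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1L, ]
      i <- min(ij); j <- max(ij)
      # near-collinear pair: the homogeneous form is the stable combination
      # (estimated effect vectors put amplified noise on the Psi^-1
      # contrast direction)
      cand <- combine_pair_mat(Tm[, c(i, j)], SE[, c(i, j)], B[, c(i, j)],
                               Psi_cur[c(i, j), c(i, j)],
                               hom_effect_model(2L), compute_p = FALSE)
      cand$variant <- "hom"
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        pair = paste0(labels[i], "|", labels[j]), variant = cand$variant,
        action = "forced", K_after = K - 1L)
      apply_combination(i, j, cand)
      U <- U + 1L
      next
    }
    # D is fixed within a sweep: rejections only mask entries, and any
    # acceptance breaks out to recompute everything on the reduced panel
    em <- estimate_effect_model(list(t = Tm, se = SE), Psi_cur, "all")
    D <- abs(em$Pi - Psi_cur)
    diag(D) <- 0
    repeat {
      if (max(D) <= F) break
      ij <- which(D == max(D), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1L, ]
      i <- min(ij); j <- max(ij)
      cand <- combine_at(i, j)
      wald2 <- row_quadform(Tm[, c(i, j)], Psi_cur[c(i, j), c(i, j)])
      Kc <- ncol(Tm)
      accepted <- cand$ok &&
        evaluate_fast(cand$t, wald2, Tm[, c(i, j)]^2,
                      npairs = Kc * (Kc - 1) / 2)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        pair = paste0(labels[i], "|", labels[j]), variant = cand$variant,
        action = if (accepted) "accepted" else "rejected",
        K_after = K - accepted)
      if (accepted) {
        apply_combination(i, j, cand)
        U <- U + 1L
        break  # redo the forced pass and refresh D on the reduced panel
      } else {
        D[i, j] <- D[j, i] <- 0
      }
    }
    if (ncol(Tm) == K) break  # nothing accepted in this sweep
  }

  Pmat <- p_from_t(Tm)
  out <- gwas_panel(panel$variants, beta = B, se = SE, n = N, t = Tm,
                    p = Pmat, labels = labels)
  state <- structure(list(
    U = U, Psi = Psi_cur, Psi0 = Psi, coef = Acum,
    log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(pair = character(), variant = character(),
                 action = character(), K_after = integer())
  ), class = "iebicow_state")
  list(panel = out, state = state)
}

#' @export
print.iebicow_state <- function(x, ...) {
  cat(sprintf("i-EbICoW: %d combination(s) accepted, %d studies out\n",
              x$U, nrow(x$coef)))
  invisible(x)
}
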