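#' Threshold grid for the truncated Wald test
#'
#' By default the grid is `r_q = 10^(-q/3)` for `q = 1..Q` with `Q = 18`,
#' spanning ~0.46 down to 1e-6 in uniform log steps.
#'
#' @param Q Number of thresholds (default 18).
#' @param r Optional explicit threshold vector, strictly descending in
#'   `[0, 1)`.
#' @return Object of class `twt_config` with elements `r` and `Q`.
#' @export
twt_config <- function(Q = 18L, r = NULL) {
  if (is.null(r)) r <- 10^(-(seq_len(Q) / 3))
  Q <- length(r)
  stopifnot(all(r < 1), all(r >= 0), all(diff(r) < 0))
  structure(list(r = r, Q = Q), class = "twt_config")
}

#' Wald test on a subset of GWAS statistics
#'
#' The quadratic form `t^T Psi^-1 t`, chi-squared with `length(t)` degrees
#' of freedom under the null of no effect in any included study.
#'
#' @param t_sub Vector of T statistics of the subset.
#' @param Psi_sub Background-correlation matrix of the subset.
#' @return List with `stat`, `df`, `p`.
#' @export
wald_statistic <- function(t_sub, Psi_sub) {
  Psi_sub <- as.matrix(Psi_sub)
  stopifnot(length(t_sub) == nrow(Psi_sub))
  stat <- drop(t_sub %*% solve(Psi_sub, t_sub))
  df <- length(t_sub)
  list(stat = stat, df = df, p = chisq_sf(stat, df))
}

#' Truncated Wald scan of one variant
#'
#' For each threshold `r_q`, performs a Wald test on the sub-vector of
#' statistics whose single-study p-value is at most `r_q` (using the
#' matching principal submatrix of `Psi`); entry q is `NA` when the subset
#' is empty. The last entry (index `Q + 1`) is the minimum single-study
#' p-value, the one-element-subset limit of the scan.
#'
#' @param p_vec,t_vec Aligned K-vectors of p-values and T statistics.
#' @param Psi K x K background-correlation matrix.
#' @param config A [twt_config()].
#' @return Numeric vector `cp` of length `Q + 1`.
#' @export
twt_scan <- function(p_vec, t_vec, Psi, config = twt_config()) {
  r <- config$r
  cp <- rep(NA_real_, config$Q + 1L)
  for (q in seq_along(r)) {
    id <- which(p_vec <= r[q])
    if (length(id) == 0L) next
    cp[q] <- wald_statistic(t_vec[id], Psi[id, id])$p
  }
  cp[config$Q + 1L] <- min(p_vec)
  cp
}

#' Truncated Wald scan of a whole panel
#'
#' Row-wise [twt_scan()] over all M variants, vectorized by grouping
#' variants that share the same study subset at each threshold (one
#' matrix inversion per distinct subset, cached across thresholds).
#'
#' @param panel A [gwas_panel()] (typically the i-EbICoW output).
#' @param Psi Background-correlation matrix of the panel's studies.
#' @param config A [twt_config()].
#' @return M x (Q + 1) matrix `CP` of combined p-values (`NA` marks empty
#'   subsets).
#' @export
twt_genome <- function(panel, Psi, config = twt_config()) {
  twt_genome_mat(panel$t, panel$p, Psi, config)
}

twt_genome_mat <- function(Tmat, Pmat, Psi, config = twt_config()) {
  M <- nrow(Tmat)
  K <- ncol(Tmat)
  r <- config$r
  Q <- config$Q
  CP <- matrix(NA_real_, M, Q + 1L)
  CP[, Q + 1L] <- do.call(pmin, asplit(Pmat, 2L))
  pow2 <- 2^(seq_len(K) - 1L)
  inv_cache <- new.env(parent = emptyenv())
  for (q in seq_len(Q)) {
    member <- Pmat <= r[q]
    key <- drop((member * 1) %*% pow2)   # exact for K <= 52
    ord <- order(key, method = "radix")  # group variants by subset pattern
    ks <- key[ord]
    starts <- which(c(TRUE, ks[-1L] != ks[-M]))
    ends <- c(starts[-1L] - 1L, M)
    for (g in seq_along(starts)) {
      if (ks[starts[g]] == 0) next
      rows <- ord[starts[g]:ends[g]]
      ids <- which(member[rows[1L], ])
      df <- length(ids)
      if (df == 1L) {
        stat <- Tmat[rows, ids]^2
      } else {
        kname <- as.character(ks[starts[g]])
        inv <- get0(kname, inv_cache)
        if (is.null(inv)) {
          inv <- solve(Psi[ids, ids])
          assign(kname, inv, inv_cache)
        }
        Ts <- Tmat[rows, ids, drop = FALSE]
        stat <- rowSums((Ts %*% inv) * Ts)
      }
      CP[rows, q] <- chisq_sf(stat, df)
    }
  }
  CP
}
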