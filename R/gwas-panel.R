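#' Construct a panel of aligned GWAS summary statistics
#'
#' A `gwas_panel` holds K GWASs aligned on a shared set of M variants. For
#' speed, the per-variant statistics are stored as M x K matrices (`beta`,
#' `se`, `n`, `t`, `p`) together with a variant table (id, alleles, optional
#' coordinates, taken from the first study) and K trait labels. Use
#' [harmonize_panel()] to build one from raw [gwas_table()]s;
#' `panel_table(panel, k)` extracts study k back as a `gwas_table`.
#'
#' @param variants Data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele` and optionally `chrom`, `pos` (M rows).
#' @param beta,se,n,t,p M x K numeric matrices.
#' @param labels Character vector of K trait names.
#' @return A list of class `gwas_panel`.
#' @export
gwas_panel <- function(variants, beta, se, n, t, p, labels = NULL) {
  M <- nrow(variants)
  K <- ncol(t)
  stopifnot(M >= 1L, K >= 1L,
            all(vapply(list(beta, se, n, t, p),
                       function(m) identical(dim(m), c(M, K)), logical(1))))
  if (is.null(labels)) labels <- paste0("gwas", seq_len(K))
  structure(list(variants = variants, beta = beta, se = se, n = n,
                 t = t, p = p, labels = labels),
            class = "gwas_panel")
}

#' @export
print.gwas_panel <- function(x, ...) {
  cat(sprintf("gwas_panel: %d variants x %d studies (%s)\n",
              nrow(x$variants), ncol(x$t),
              paste(utils::head(x$labels, 5), collapse = ", ")))
  invisible(x)
}

#' Number of variants / studies in a panel
#' @param panel A [gwas_panel()].
#' @return Integer count.
#' @export
panel_m <- function(panel) nrow(panel$variants)

#' @rdname panel_m
#' @export
panel_k <- function(panel) ncol(panel$t)

#' Extract one study of a panel as a `gwas_table`
#' @param panel A [gwas_panel()].
#' @param k Study index.
#' @return A [gwas_table()].
#' @export
panel_table <- function(panel, k) {
  v <- panel$variants
  gwas_table(v$variant_id, v$effect_allele, v$other_allele,
             beta = panel$beta[, k], se = panel$se[, k], n = panel$n[, k],
             t = panel$t[, k], p = panel$p[, k],
             chrom = v$chrom %||% NA_character_, pos = v$pos %||% NA_integer_)
}

#' Harmonize K GWAS tables into an aligned panel
#'
#' Restricts all tables to the intersection of their variant ids (in the
#' order of the first table), and aligns allele coding to the first table:
#' variants whose (effect, other) allele pair is the swap of the first
#' table's pair have `beta` and `t` sign-flipped and alleles swapped;
#' variants with incompatible allele pairs in any table are removed
#' panel-wide. Strand-ambiguous variants (A/T, C/G) are kept as-is with a
#' warning. Harmonization is idempotent.
#'
#' @param tables List of K [gwas_table()]s.
#' @param labels Optional K trait names (defaults to list names).
#' @return A [gwas_panel()].
#' @export
harmonize_panel <- function(tables, labels = NULL) {
  K <- length(tables)
  stopifnot(K >= 1L)
  if (is.null(labels)) labels <- names(tables) %||% paste0("gwas", seq_len(K))
  ids <- tables[[1L]]$variant_id
  for (k in seq_len(K)[-1]) ids <- ids[ids %in% tables[[k]]$variant_id]
  if (length(ids) == 0L) stop("empty variant intersection across tables")

  ref <- tables[[1L]][match(ids, tables[[1L]]$variant_id), , drop = FALSE]
  ambiguous <- (ref$effect_allele == "A" & ref$other_allele == "T") |
    (ref$effect_allele == "T" & ref$other_allele == "A") |
    (ref$effect_allele == "C" & ref$other_allele == "G") |
    (ref$effect_allele == "G" & ref$other_allele == "C")
  if (any(ambiguous)) {
    warning(sum(ambiguous), " strand-ambiguous (A/T or C/G) variants kept as-is")
  }

  M <- length(ids)
  mats <- lapply(c("beta", "se", "n", "t", "p"),
                 function(f) matrix(NA_real_, M, K))
  names(mats) <- c("beta", "se", "n", "t", "p")
  keep <- rep(TRUE, M)
  for (k in seq_len(K)) {
    tk <- tables[[k]][match(ids, tables[[k]]$variant_id), , drop = FALSE]
    same <- tk$effect_allele == ref$effect_allele &
      tk$other_allele == ref$other_allele
    swap <- tk$effect_allele == ref$other_allele &
      tk$other_allele == ref$effect_allele
    keep <- keep & (same | swap)
    flip <- ifelse(swap, -1, 1)
    mats$beta[, k] <- tk$beta * flip
    mats$t[, k] <- tk$t * flip
    mats$se[, k] <- tk$se
    mats$n[, k] <- tk$n
    mats$p[, k] <- tk$p
  }
  if (!any(keep)) stop("no variants with compatible alleles across tables")
  v <- ref[keep, c("variant_id", "chrom", "pos",
                   "effect_allele", "other_allele")]
  rownames(v) <- NULL
  gwas_panel(v,
             beta = mats$beta[keep, , drop = FALSE],
             se = mats$se[keep, , drop = FALSE],
             n = mats$n[keep, , drop = FALSE],
             t = mats$t[keep, , drop = FALSE],
             p = mats$p[keep, , drop = FALSE],
             labels = labels)
}

#' Drop variants genotyped in a reduced subsample
#'
#' Removes, panel-wide, every variant whose sample size in any study falls
#' below `min_frac` of that study's maximum sample size. Variants measured in
#' a much reduced subsample have noisier effect estimates, which inflates the
#' error of the effect-correlation estimate and hurts combination power.
#'
#' @param panel A [gwas_panel()] whose `n` matrix is filled in.
#' @param min_frac Minimum retained fraction of each study's maximum n
#'   (default 0.6).
#' @return The filtered [gwas_panel()].
#' @export
filter_by_sample_size <- function(panel, min_frac = 0.6) {
  stopifnot(min_frac > 0, min_frac <= 1)
  nmax <- apply(panel$n, 2L, max, na.rm = TRUE)
  ok <- rowSums(sweep(panel$n, 2L, min_frac * nmax, `<`)) == 0
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop("all variants removed by the sample-size filter")
  subset_panel(panel, which(ok))
}

subset_panel <- function(panel, idx) {
  v <- panel$variants[idx, , drop = FALSE]
  rownames(v) <- NULL
  gwas_panel(v,
             beta = panel$beta[idx, , drop = FALSE],
             se = panel$se[idx, , drop = FALSE],
             n = panel$n[idx, , drop = FALSE],
             t = panel$t[idx, , drop = FALSE],
             p = panel$p[idx, , drop = FALSE],
             labels = panel$labels)
}

#' Systematic subsamples of approximately unlinked variants
#'
#' Returns `rounds` index subsets obtained by systematic sampling: every
#' `floor(M / target_count)`-th variant in genomic order (input order when
#' positions are absent), each round starting from a distinct random offset.
#' Estimators run on such subsets and combine the per-round estimates by the
#' median, which suppresses the effect of local linkage disequilibrium
#' without requiring LD information.
#'
#' @param panel A [gwas_panel()].
#' @param target_count Number of variants per subset (default
#'   `min(M, 1e5)`).
#' @param rounds Number of subsets (default 5).
#' @param seed Integer seed for the random offsets.
#' @return List of `rounds` integer index vectors.
#' @export
sample_unlinked <- function(panel, target_count = NULL, rounds = 5L,
                            seed = 1L) {
  M <- panel_m(panel)
  if (is.null(target_count)) target_count <- min(M, 100000L)
  stopifnot(target_count >= 2L, M >= target_count)
  ord <- seq_len(M)
  if (!is.null(panel$variants$pos) && !anyNA(panel$variants$pos)) {
    ord <- order(panel$variants$chrom, panel$variants$pos)
  }
  stride <- max(1L, M %/% target_count)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  offsets <- if (rounds >= stride) {
    rep_len(seq_len(stride), rounds)
  } else {
    sample.int(stride, rounds)
  }
  lapply(offsets, function(off) {
    idx <- seq.int(off, M, by = stride)
    sort(ord[utils::head(idx, target_count)])
  })
}
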