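#' Construct a per-variant GWAS summary-statistics table
#'
#' A `gwas_table` is a data.frame with one row per variant holding the usual
#' single-trait GWAS summary statistics: effect size `beta`, standard error
#' `se`, sample size `n`, T statistic `t = beta/se`, and the two-sided
#' p-value `p` (upper-tail 1-df chi-squared probability of `t^2`). Missing
#' `t`/`p` are filled in from `beta`/`se`; missing `beta`/`se` are filled in
#' from `t` with `se = 1`.
#'
#' @param variant_id Character vector of unique variant identifiers.
#' @param effect_allele,other_allele Character vectors of alleles; the effect
#'   of `beta` is counted per copy of `effect_allele`.
#' @param beta,se Effect sizes and standard errors (`se > 0`).
#' @param n Per-variant sample sizes (optional; default `NA`).
#' @param t T statistics (optional; derived from `beta/se` when absent).
#' @param p P-values (optional; derived from `t` when absent).
#' @param chrom,pos Optional chromosome labels and 1-based positions.
#' @return A data.frame of class `gwas_table`.
#' @export
gwas_table <- function(variant_id, effect_allele, other_allele,
                       beta = NULL, se = NULL, n = NA_integer_,
                       t = NULL, p = NULL, chrom = NA_character_,
                       pos = NA_integer_) {
  if (is.null(beta) && is.null(t)) {
    stop("need either (beta, se) or t")
  }
  if (is.null(t)) t <- beta / se
  if (is.null(beta)) {
    se <- rep_len(1, length(t))
    beta <- t
  }
  if (is.null(p)) p <- p_from_t(t)
  tab <- data.frame(
    variant_id = as.character(variant_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    n = as.numeric(n),
    t = as.numeric(t),
    p = as.numeric(p),
    stringsAsFactors = FALSE
  )
  validate_gwas_table(tab)
}

validate_gwas_table <- function(tab) {
  if (anyDuplicated(tab$variant_id)) stop("duplicated variant_id values")
  if (any(tab$se <= 0, na.rm = TRUE)) stop("non-positive standard errors")
  bad_t <- is.finite(tab$beta) & is.finite(tab$se) &
    abs(tab$t - tab$beta / tab$se) > 1e-6 * pmax(1, abs(tab$t))
  if (any(bad_t, na.rm = TRUE)) stop("t inconsistent with beta/se")
  class(tab) <- c("gwas_table", "data.frame")
  tab
}

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text table of per-variant summary statistics. Column
#' names are resolved through `column_map`, a named list/vector mapping the
#' canonical names (`variant_id`, `effect_allele`, `other_allele`, `beta`,
#' `se`, `n`, `t`, `p`, `chrom`, `pos`) to the header names in the file. At
#' minimum the file must provide the variant id, both alleles, and either
#' (`beta`, `se`) or `t`. Rows with missing or non-finite required fields
#' (including `se <= 0`) are dropped; the number dropped is reported via
#' `message()` and stored in the `n_dropped` attribute.
#'
#' @param path Path to a tab- (or otherwise) delimited text file with header.
#' @param column_map Named character vector/list mapping canonical column
#'   names to file headers. Canonical names already present in the file need
#'   not be mapped.
#' @param sep Field separator (default `"auto"`, as in [data.table::fread()]).
#' @return A [gwas_table()].
#' @export
read_gwas <- function(path, column_map = NULL, sep = "auto") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  dt <- data.table::fread(path, sep = sep, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) stop("zero usable rows in ", path)
  nm <- names(dt)
  pick <- function(canon) {
    mapped <- if (!is.null(column_map) && canon %in% names(column_map)) {
      as.character(column_map[[canon]])
    } else canon
    if (mapped %in% nm) dt[[mapped]] else NULL
  }
  vid <- pick("variant_id")
  ea <- pick("effect_allele")
  oa <- pick("other_allele")
  if (is.null(vid) || is.null(ea) || is.null(oa)) {
    stop("missing required columns (variant_id/effect_allele/other_allele)")
  }
  beta <- pick("beta"); se <- pick("se"); tt <- pick("t")
  if ((is.null(beta) || is.null(se)) && is.null(tt)) {
    stop("need either (beta, se) columns or a t column")
  }
  n <- pick("n") %||% rep(NA_real_, nrow(dt))
  p <- pick("p")
  chrom <- pick("chrom") %||% rep(NA_character_, nrow(dt))
  pos <- pick("pos") %||% rep(NA_integer_, nrow(dt))

  if (!is.null(beta) && !is.null(se)) {
    ok <- is.finite(beta) & is.finite(se) & se > 0
  } else {
    ok <- is.finite(tt)
  }
  ok <- ok & !is.na(vid) & !is.na(ea) & !is.na(oa)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message("read_gwas: dropped ", n_dropped,
            " rows with missing/invalid required fields")
  }
  if (!any(ok)) stop("zero usable rows in ", path)
  keep <- which(ok)
  tab <- gwas_table(
    variant_id = vid[keep], effect_allele = ea[keep], other_allele = oa[keep],
    beta = if (is.null(beta)) NULL else beta[keep],
    se = if (is.null(se)) NULL else se[keep],
    n = n[keep],
    t = if (is.null(tt)) NULL else tt[keep],
    p = if (is.null(p)) NULL else p[keep],
    chrom = chrom[keep], pos = pos[keep]
  )
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write combined results to a delimited text file
#'
#' Writes the final per-variant results as a tab-separated table that
#' round-trips through [data.table::fread()]. P-values are written in
#' scientific notation with at least 6 significant digits.
#'
#' @param variant_index Character vector of M variant ids.
#' @param p_values Numeric vector of M combined p-values.
#' @param annotations Optional data.frame of M rows with extra columns
#'   (chromosome, position, winning subset size, stage flags, ...).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_results <- function(variant_index, p_values, annotations = NULL, path) {
  stopifnot(length(variant_index) == length(p_values))
  out <- data.frame(variant_id = as.character(variant_index),
                    p = format(p_values, digits = 15, scientific = TRUE),
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    stopifnot(nrow(annotations) == length(p_values))
    out <- cbind(out, annotations)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
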