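# Build a gwas_panel directly from a T-statistic matrix (se = 1, beta = t),
# the working representation of the summary-statistics simulations.
panel_from_t <- function(Tm, se = 1, n = 10000) {
  M <- nrow(Tm)
  K <- ncol(Tm)
  v <- data.frame(variant_id = paste0("snp", seq_len(M)),
                  chrom = "1", pos = seq_len(M),
                  effect_allele = "A", other_allele = "G",
                  stringsAsFactors = FALSE)
  SE <- matrix(se, M, K)
  gwas_panel(v, beta = Tm * se, se = SE, n = matrix(n, M, K),
             t = Tm, p = p_from_t(Tm))
}

# Exchangeable correlation matrix shortcut used across tests.
exch <- function(K, rho) {
  S <- matrix(rho, K, K)
  diag(S) <- 1
  S
}

# Correlated null draws.
draw_mvn <- function(n, Sigma, seed) {
  set.seed(seed)
  matrix(rnorm(n * nrow(Sigma)), n, nrow(Sigma)) %*% chol(Sigma)
}

# Small gwas_table fixture with explicit alleles.
toy_table <- function(ids, ea, oa, beta, se, n = 1000) {
  gwas_table(ids, ea, oa, beta = beta, se = se, n = n)
}
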