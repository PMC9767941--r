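test_that("read_gwas derives t and p from beta/se and drops invalid rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"),
                   A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
                   BETA = c(0.1, 0, 0.3), SE = c(0.05, 1, 0),
                   N = c(100, 100, 100))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- suppressMessages(read_gwas(f, column_map = c(
    variant_id = "SNP", effect_allele = "A1", other_allele = "A2",
    beta = "BETA", se = "SE", n = "N")))
  expect_equal(nrow(tab), 2L)              # se = 0 row dropped
  expect_equal(attr(tab, "n_dropped"), 1L)
  expect_equal(tab$t, c(2, 0))
  expect_equal(tab$p[1], pchisq(4, 1, lower.tail = FALSE))
  expect_equal(tab$p[2], 1)

  expect_error(read_gwas(f, column_map = c(variant_id = "nope")),
               "required columns")
  expect_error(read_gwas(file.path(tempdir(), "missing-xyz.tsv")),
               "cannot read")
})

test_that("gwas_table enforces its invariants", {
  expect_error(toy_table(c("a", "a"), "A", "G", c(1, 2), c(1, 1)),
               "duplicated")
  expect_error(toy_table("a", "A", "G", 1, -1), "standard errors")
  expect_error(gwas_table("a", "A", "G", beta = 1, se = 1, t = 5),
               "inconsistent")
})

test_that("harmonize_panel flips swapped alleles and drops incompatible ones", {
  g1 <- toy_table(c("v1", "v2", "v3"), c("A", "C", "A"), c("G", "T", "C"),
                  beta = c(0.2, 0.1, 0.1), se = c(0.1, 0.1, 0.1))
  # v1 swapped (flip), v2 same, v3 incompatible alleles
  g2 <- toy_table(c("v1", "v2", "v3"), c("G", "C", "A"), c("A", "T", "G"),
                  beta = c(0.2, 0.3, 0.1), se = c(0.1, 0.1, 0.1))
  pan <- harmonize_panel(list(g1, g2))
  expect_equal(pan$variants$variant_id, c("v1", "v2"))
  expect_equal(pan$t[1, 2], -2)            # flipped sign
  expect_equal(pan$t[2, 2], 3)

  # idempotence: harmonizing the extracted tables changes nothing
  pan2 <- harmonize_panel(list(panel_table(pan, 1), panel_table(pan, 2)))
  expect_equal(pan2$t, pan$t)
  expect_equal(pan2$variants$variant_id, pan$variants$variant_id)

  # identity: identical tables keep all variants
  pan3 <- harmonize_panel(list(g1, g1))
  expect_equal(panel_m(pan3), 3L)
  expect_error(harmonize_panel(list(
    g1, toy_table("zz", "A", "G", 1, 1))), "intersection")
})

test_that("whole-table allele flips do not change the harmonized panel", {
  set.seed(11)
  Tm <- matrix(rnorm(200), 100, 2)
  ids <- paste0("v", 1:100)
  g1 <- toy_table(ids, "A", "G", Tm[, 1], rep(1, 100))
  g2 <- toy_table(ids, "A", "G", Tm[, 2], rep(1, 100))
  g2_flipped <- toy_table(ids, "G", "A", -Tm[, 2], rep(1, 100))
  p1 <- harmonize_panel(list(g1, g2))
  p2 <- harmonize_panel(list(g1, g2_flipped))
  expect_equal(p1$t, p2$t)
  expect_equal(p1$beta, p2$beta)
})

test_that("sample-size filter removes low-n variants panel-wide", {
  set.seed(2)
  Tm <- matrix(rnorm(20), 10, 2)
  pan <- panel_from_t(Tm)
  pan$n[1:3, 1] <- 5000   # 50% of the max 10000
  out <- filter_by_sample_size(pan, min_frac = 0.6)
  expect_equal(panel_m(out), 7L)
  expect_true(all(out$n >= 0.6 * 10000))

  # all equal: nothing removed
  expect_equal(panel_m(filter_by_sample_size(pan, min_frac = 0.4)), 10L)
  # exactly at the boundary is kept
  pan$n[4, 2] <- 6000
  out2 <- filter_by_sample_size(pan, min_frac = 0.6)
  expect_true("snp4" %in% out2$variants$variant_id)
})

test_that("systematic unlinked sampling uses constant stride and offsets", {
  pan <- panel_from_t(matrix(rnorm(200), 100, 2))
  s1 <- sample_unlinked(pan, target_count = 10, rounds = 1, seed = 1)
  expect_length(s1, 1L)
  expect_length(s1[[1]], 10L)
  expect_true(all(diff(s1[[1]]) == 10L))

  s5 <- sample_unlinked(pan, target_count = 10, rounds = 5, seed = 1)
  offsets <- vapply(s5, `[`, numeric(1), 1L)
  expect_equal(length(unique(offsets)), 5L)

  pan10 <- panel_from_t(matrix(rnorm(20), 10, 2))
  expect_equal(sample_unlinked(pan10, 10, rounds = 1, seed = 1)[[1]], 1:10)
  expect_error(sample_unlinked(pan, target_count = 1), "target_count")
})

test_that("results round-trip through write_results", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ids <- paste0("v", 1:5)
  p <- c(1.234567e-12, 0.5, 0.04999, 1, 3.3e-300)
  write_results(ids, p, annotations = data.frame(chrom = "1", pos = 1:5), f)
  back <- data.table::fread(f, data.table = FALSE)
  expect_equal(back$p, p, tolerance = 1e-12)
  expect_equal(back$variant_id, ids)

  # minimal two-column output
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(ids, p, path = f2)
  expect_equal(ncol(data.table::fread(f2)), 2L)
})
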