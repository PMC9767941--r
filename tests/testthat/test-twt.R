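test_that("Wald statistic matches hand-computed quadratic forms", {
  r0 <- wald_statistic(c(0, 0), diag(2))
  expect_equal(r0$stat, 0)
  expect_equal(r0$p, 1)

  r1 <- wald_statistic(c(2, 0), diag(2))
  expect_equal(r1$stat, 4)
  expect_equal(r1$p, exp(-2), tolerance = 1e-12)

  r2 <- wald_statistic(c(2, 2), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(r2$stat, 16 / 3, tolerance = 1e-12)
  expect_equal(r2$df, 2L)
})

test_that("threshold grid is descending and defaults to 10^(-q/3)", {
  cfg <- twt_config()
  expect_equal(cfg$Q, 18L)
  expect_equal(cfg$r, 10^(-(1:18) / 3))
  expect_error(twt_config(r = c(0.1, 0.2)), "diff")
})

test_that("per-variant scan handles singletons, empty subsets and the min column", {
  cfg <- twt_config()
  # K = 1: the scan is the input p wherever the subset is non-empty
  cp1 <- twt_scan(0.01, qnorm(0.005), diag(1), cfg)
  expect_equal(cp1[cfg$Q + 1L], 0.01)
  expect_equal(cp1[seq_len(cfg$Q)][cfg$r >= 0.01], rep(0.01, 6),
               tolerance = 1e-10)
  expect_true(all(is.na(cp1[seq_len(cfg$Q)][cfg$r < 0.01])))

  # all large p: every threshold subset empty
  cp2 <- twt_scan(c(0.5, 0.5), c(0.67, 0.67), diag(2), cfg)
  expect_true(all(is.na(cp2[1:cfg$Q])))
  expect_equal(cp2[cfg$Q + 1L], 0.5)

  # mixed: one strong study, one weak-but-included at the loosest threshold
  t <- c(3, 1.2)
  p <- p_from_t(t)   # (0.0027, 0.230)
  cp3 <- twt_scan(p, t, diag(2), cfg)
  expect_equal(cp3[6], p[1], tolerance = 1e-10)   # singleton {1} at r = 0.01
  expect_equal(cp3[1], chisq_sf(sum(t^2), 2))     # both in at r_1 = 0.464
  expect_equal(cp3[3], p[1], tolerance = 1e-10)   # only {1} at r_3 = 0.1
})

test_that("scan is invariant to study reordering", {
  set.seed(31)
  K <- 5
  Psi <- cov2cor(crossprod(matrix(rnorm(K * K), K)) + diag(K))
  t <- rnorm(K, 0, 1.5)
  p <- p_from_t(t)
  perm <- sample(K)
  cp_a <- twt_scan(p, t, Psi)
  cp_b <- twt_scan(p[perm], t[perm], Psi[perm, perm])
  expect_equal(cp_a, cp_b, tolerance = 1e-12)
})

test_that("genome scan equals row-wise scans and is deterministic", {
  set.seed(32)
  Psi <- exch(4, 0.3)
  Tm <- draw_mvn(500, Psi, seed = 32)
  Pm <- p_from_t(Tm)
  CP <- cgwas:::twt_genome_mat(Tm, Pm, Psi, twt_config())
  for (m in c(1, 57, 500)) {
    expect_equal(CP[m, ], twt_scan(Pm[m, ], Tm[m, ], Psi), tolerance = 1e-12)
  }
  # duplicated variant rows give identical scan rows
  Tm2 <- rbind(Tm, Tm[7, ])
  CP2 <- cgwas:::twt_genome_mat(Tm2, p_from_t(Tm2), Psi, twt_config())
  expect_equal(CP2[501, ], CP2[7, ])

  # with Psi = I, the full-subset column is the chi-squared of sum t^2
  CPI <- cgwas:::twt_genome_mat(Tm, Pm, diag(4), twt_config())
  all_in <- rowSums(Pm <= twt_config()$r[1]) == 4
  expect_equal(CPI[all_in, 1], chisq_sf(rowSums(Tm[all_in, ]^2), 4))
})

test_that("adding an uninformative null study never decreases the full-set scan p", {
  set.seed(33)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    t <- rnorm(K, 0, 2)
    stat_k <- drop(t %*% t)
    p_small <- chisq_sf(stat_k, K)
    p_plus <- chisq_sf(stat_k, K + 1L)   # t = 0 adds 0 to the form, +1 df
    expect_gte(p_plus, p_small)
  }
})
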