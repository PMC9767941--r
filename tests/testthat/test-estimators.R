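test_that("inflation estimate recovers s on null and inflated panels", {
  set.seed(101)
  fit0 <- estimate_inflation(rnorm(1e5))
  expect_lt(abs(fit0$s - 1), 0.02)
  expect_equal(fit0$s, fit0$I + 1)

  fit2 <- estimate_inflation(rnorm(1e5, 0, sqrt(1.2)))
  expect_lt(abs(fit2$s - 1.2), 0.02)
})

test_that("inflation estimate separates true effects where genomic control cannot", {
  set.seed(102)
  M <- 1e5
  t <- rnorm(M, 0, sqrt(1.1))
  t[1:20000] <- t[1:20000] + rnorm(20000, 0, sqrt(2))
  fit <- estimate_inflation(t)
  expect_lt(abs(fit$s - 1.1), 0.03)
  expect_gt(fit$Lambda, 1)          # effect variance attributed to Lambda
  expect_gt(lambda_gc(t), 1.2)      # median-ratio comparator is inflated
})

test_that("inflation adjustment rescales t and se but not beta", {
  tab <- toy_table(paste0("v", 1:4), "A", "G",
                   beta = c(2, -1, 0.5, 0), se = c(1, 1, 0.25, 1))
  adj <- adjust_inflation(tab, s = 4)
  expect_equal(adj$t, tab$t / 2)
  expect_equal(adj$beta, tab$beta)
  expect_equal(adj$se, tab$se * 2)
  expect_equal(adj$p, p_from_t(adj$t))
  expect_equal(adjust_inflation(tab, 1), tab)
  expect_error(adjust_inflation(tab, 0.5), ">= 1")
})

test_that("background-correlation estimate is symmetric, sign-stable and clamps", {
  set.seed(103)
  Tm <- draw_mvn(2e4, exch(2, 0.4), seed = 103)
  p12 <- estimate_psi(Tm[, 1], Tm[, 2])
  expect_equal(p12, estimate_psi(Tm[, 2], Tm[, 1]))
  expect_equal(p12, estimate_psi(-Tm[, 1], -Tm[, 2]))
  expect_lt(abs(p12 - 0.4), 0.05)

  t <- rnorm(2000)
  expect_equal(estimate_psi(t, t), 0.999)  # clamp at perfect correlation
})

test_that("background-correlation matrix handles independence and duplicates", {
  set.seed(104)
  Tm <- matrix(rnorm(3e4 * 3), 3e4, 3)
  Psi <- estimate_psi_matrix(panel_from_t(Tm))
  expect_equal(diag(Psi), rep(1, 3))
  expect_lt(max(abs(Psi[upper.tri(Psi)])), 0.05)

  Tm2 <- cbind(Tm[, 1], Tm[, 1], Tm[, 2])
  Psi2 <- suppressMessages(estimate_psi_matrix(panel_from_t(Tm2)))
  expect_lt(Psi2[1, 2], 1)
  expect_no_error(solve(Psi2))
})

test_that("effect-correlation estimate recovers Pi and floors null diagonals", {
  set.seed(105)
  M <- 2e5
  Tm <- matrix(rnorm(M * 2), M, 2)
  Sig <- matrix(c(3, 0.8 * 3, 0.8 * 3, 3), 2)
  eff <- draw_mvn(M / 10, Sig, seed = 106)
  Tm[seq_len(M / 10), ] <- Tm[seq_len(M / 10), ] + eff
  em <- estimate_effect_model(panel_from_t(Tm), diag(2), "all")
  expect_lt(abs(em$Pi[1, 2] - 0.8), 0.05)
  expect_equal(em$sign_row, c(1, 1))

  # pure null: diagonal floored, Pi still defined
  Tm0 <- matrix(rnorm(2e4 * 2), 2e4, 2)
  em0 <- estimate_effect_model(panel_from_t(Tm0), diag(2), "all")
  expect_true(all(diag(em0$A) >= 0.001))
  expect_true(all(is.finite(em0$Pi)))
  expect_true(all(abs(em0$Pi) <= 1))

  # stb: all-ones effect correlation regardless of data
  em_stb <- estimate_effect_model(panel_from_t(Tm0), diag(2), "stb")
  expect_equal(em_stb$Pi, matrix(1, 2, 2))

  # sig with too few significant variants falls back to all
  expect_warning(
    em_sig <- estimate_effect_model(panel_from_t(Tm0), diag(2), "sig"),
    "falling back")
  expect_equal(em_sig$variant, "all")
})
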