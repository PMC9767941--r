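test_that("Tippett adjustment matches closed forms", {
  expect_equal(tippett_adjust(0.5, 1), 0.5)
  expect_equal(tippett_adjust(0.01, 10), 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(tippett_adjust(0, 7), 0)
  expect_equal(tippett_adjust(1, 3), 1)
  # precision for tiny p: 1 - (1-p)^N ~ N p
  expect_equal(tippett_adjust(1e-300, 2), 2e-300, tolerance = 1e-6)
})

test_that("effective test number recovers the independent-minimum case", {
  set.seed(41)
  U <- matrix(runif(5e5), ncol = 5)
  col_min <- do.call(pmin, asplit(U, 2))
  expect_lt(abs(estimate_n_independent(col_min) - 5), 0.5)
  expect_lt(abs(estimate_n_independent(runif(1e5)) - 1), 0.15)
  # perfect dependence: the minimum of 5 copies of one uniform is uniform
  x <- runif(1e5)
  expect_lt(abs(estimate_n_independent(pmin(x, x, x, x, x)) - 1), 0.15)
  expect_error(estimate_n_independent(runif(100)), "1e4")
})

test_that("quantile-coefficient calibration maps known nulls to uniform", {
  set.seed(42)
  n <- 2e5
  fresh <- function(x, curve) {
    suppressWarnings(ks.test(apply_calibration(x, curve), "punif"))$p.value
  }
  # already uniform: curve is near identity
  u0 <- runif(n)
  c0 <- fit_quantile_coefficients(u0)
  expect_lt(max(abs(predict(c0, c(0.01, 0.1, 0.5)) - 1)), 0.05)
  expect_gt(fresh(runif(n), c0), 0.01)

  # stochastically small null U^2: analytic quantile u^2, c(u) ~ 1/u
  c1 <- fit_quantile_coefficients(runif(n)^2)
  expect_gt(fresh(runif(n)^2, c1), 0.01)
  expect_lt(abs(predict(c1, 0.01) - 100) / 100, 0.25)

  # minimum of two independent uniforms
  m2 <- pmin(runif(n), runif(n))
  c2 <- fit_quantile_coefficients(m2)
  expect_gt(fresh(pmin(runif(n), runif(n)), c2), 0.01)

  # order preservation and monotonicity
  p <- sort(runif(1000))
  cal <- apply_calibration(p, c2)
  expect_true(all(diff(cal) >= 0))
  expect_error(fit_quantile_coefficients(rep(0.5, 1000)), "degenerate")
})

test_that("null simulation is seeded, moment-correct and guarded", {
  Psi <- exch(3, 0.5)
  A <- simulate_null_panel(Psi, 1e5, seed = 7)
  B <- simulate_null_panel(Psi, 1e5, seed = 7)
  expect_identical(A, B)
  expect_lt(max(abs(colMeans(A))), 3 / sqrt(1e5) * 1.5)
  expect_lt(max(abs(cor(A) - Psi)), 3 / sqrt(1e5) * 1.5)
  expect_error(simulate_null_panel(Psi, 100, 1), "NS")
})

test_that("calibrated minimum-p combination matches its closed-form nulls", {
  set.seed(43)
  # independent studies: calibrated min-p tracks the Tippett form
  Tm <- matrix(rnorm(3e4 * 3), 3e4, 3)
  pan <- panel_from_t(Tm)
  out <- mingwas(pan, diag(3), NS = 1e5, seed = 9)
  tip <- tippett_adjust(do.call(pmin, asplit(pan$p, 2)), 3)
  expect_gt(cor(out, tip), 0.999)
  expect_lt(median(abs(out - tip)), 0.02)
  # correlated studies need strictly less than a K-fold correction
  Tm2 <- draw_mvn(3e4, exch(3, 0.7), seed = 44)
  pan2 <- panel_from_t(Tm2)
  out2 <- mingwas(pan2, exch(3, 0.7), NS = 1e5, seed = 9)
  minp2 <- do.call(pmin, asplit(pan2$p, 2))
  mid <- minp2 > 0.01 & minp2 < 0.2
  expect_lt(median(out2[mid] / minp2[mid]),
            median(tippett_adjust(minp2[mid], 3) / minp2[mid]))
})

test_that("calibration model adjusts scan columns to a common scale", {
  Psi <- exch(4, 0.5)
  cal <- build_calibration(Psi, NS = 1e5, seed = 11)
  expect_s3_class(cal, "calibration_model")
  expect_length(cal$Neff, 19L)
  expect_true(all(cal$Neff >= 1))
  # calibrated null minima are uniform
  ks <- suppressWarnings(ks.test(
    apply_calibration(cal$minSP, cal$coef_curve), "punif"))
  expect_gt(ks$p.value, 1e-4)

  # fresh nulls through the same model are uniform too
  set.seed(12)
  Ts <- simulate_null_panel(Psi, 5e4, seed = 13)
  CP <- cgwas:::twt_genome_mat(Ts, p_from_t(Ts), Psi, twt_config())
  for (q in 1:19) CP[, q] <- tippett_adjust(CP[, q], cal$Neff[q])
  minp <- do.call(pmin, c(asplit(CP, 2), list(na.rm = TRUE)))
  ks2 <- suppressWarnings(ks.test(apply_calibration(minp, cal$coef_curve),
                                  "punif"))
  expect_gt(ks2$p.value, 1e-3)
})

test_that("study-wide threshold arithmetic composes the burdens", {
  expect_equal(derive_studywide_threshold(5e-8, 1, 1), 5e-8)
  expect_equal(derive_studywide_threshold(1e-6, 2, 3), 6e-6)
  expect_error(derive_studywide_threshold(5e-8, -1, 2), "ntest_burden")
})
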