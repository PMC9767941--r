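test_that("EbICoW statistic matches hand-computed cases", {
  # IVW special case: Psi = I, equal weights
  r <- ebicow_statistic(c(3, 3), c(1, 1), diag(2), c(1, 1))
  expect_equal(r$t_E, 6 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$beta_c, 3)
  expect_equal(r$se_c, 1 / sqrt(2))

  # hand-inverted 2x2 with psi = 0.9
  Psi <- matrix(c(1, 0.9, 0.9, 1), 2)
  r2 <- ebicow_statistic(c(1, 1), c(1, 1), Psi, c(1, 1))
  expect_equal(r2$t_E, sqrt(0.2 / 0.19), tolerance = 1e-12)

  # linearity: zero input gives zero regardless of h and Psi
  expect_equal(ebicow_statistic(c(0, 0), c(2, 3), Psi, c(5, -1))$t_E, 0)

  expect_error(ebicow_statistic(c(1, 1), c(1, 1), matrix(1, 2, 2), c(1, 1)),
               "singular")
})

test_that("reduction chain: EbICoW to IVW, and t_C^2 equals S_Hom", {
  set.seed(21)
  for (rep_i in 1:5) {
    K <- sample(2:5, 1)
    t <- rnorm(K); sigma <- runif(K, 0.5, 2)
    # Psi = I and h on the equal-expected-effect ray: classical IVW
    h <- 1 / sigma^2 * 3.7   # any scaling of nu o nu
    w <- (1 / sigma^2) / sum(1 / sigma^2)
    ivw_t <- sum(w * t * sigma) / sqrt(sum(w^2 * sigma^2))
    expect_equal(ebicow_statistic(t, sigma, diag(K), h * sigma^2)$t_E,
                 ivw_t, tolerance = 1e-10)

    # general Psi with homogeneous weights: S_Hom chi-squared identity
    A <- matrix(rnorm(K * K), K)
    Psi <- cov2cor(crossprod(A) + diag(K))
    e <- 1 / sigma
    tC <- drop(e %*% solve(Psi, t)) / sqrt(drop(e %*% solve(Psi, e)))
    s_hom <- drop(e %*% solve(Psi, t))^2 / drop(e %*% solve(Psi, e))
    expect_equal(ebicow_statistic(t, sigma, Psi, rep(1, K))$t_E^2, s_hom,
                 tolerance = 1e-10)
    expect_equal(tC^2, s_hom, tolerance = 1e-10)
  }
})

test_that("combining two independent same-trait GWASs is fixed-effect meta-analysis", {
  set.seed(22)
  M <- 5e4
  b <- rnorm(5e3, 0, 0.02)
  beta1 <- rnorm(M, 0, 0.01); beta2 <- rnorm(M, 0, 0.01)
  beta1[1:5e3] <- beta1[1:5e3] + b
  beta2[1:5e3] <- beta2[1:5e3] + b
  ids <- paste0("v", 1:M)
  g1 <- toy_table(ids, "A", "G", beta1, rep(0.01, M))
  g2 <- toy_table(ids, "A", "G", beta2, rep(0.01, M))
  cmb <- combine_pair(g1, g2, diag(2))
  meta_t <- (g1$t + g2$t) / sqrt(2)
  expect_gt(cor(cmb$t, meta_t), 0.999)
  # and the combined effect tracks the precision-weighted mean effect
  expect_gt(cor(cmb$beta, (beta1 + beta2) / 2), 0.999)
})

test_that("combined statistic is standard normal under the null", {
  set.seed(23)
  Tm <- draw_mvn(2e4, exch(2, 0.6), seed = 23)
  pan <- panel_from_t(Tm)
  em <- estimate_effect_model(pan, exch(2, 0.6), "stb")
  cmb <- cgwas:::combine_pair_mat(pan$t, pan$se, pan$beta, exch(2, 0.6), em)
  ks <- suppressWarnings(ks.test(cmb$t, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(cmb$t^2) - 1), 0.05)
})

test_that("evaluate rejects a combination identical to an input", {
  set.seed(24)
  M <- 2e4
  t1 <- rnorm(M); t1[1:500] <- t1[1:500] + rnorm(500, 0, 3)
  t2 <- rnorm(M)
  g_E <- list(t = t1, p = p_from_t(t1))   # "combination" = input 1
  p_wald <- chisq_sf(t1^2 + t2^2, 2)
  p_min <- pmin(p_from_t(t1), p_from_t(t2))
  expect_false(evaluate_combination(g_E, p_wald, p_min,
                                    p_inputs = cbind(p_from_t(t1),
                                                     p_from_t(t2))))
})

test_that("iterative EbICoW combines the one suitable pair and stops", {
  # studies 1, 2: fully correlated effects over psi = 0.5 background
  # (|pi - psi| = 0.5); study 3 independent null
  set.seed(25)
  M <- 5e4
  Psi <- diag(3); Psi[1, 2] <- Psi[2, 1] <- 0.5
  Tm <- draw_mvn(M, Psi, seed = 25)
  b <- rnorm(5e3, 0, sqrt(3))
  Tm[1:5e3, 1] <- Tm[1:5e3, 1] + b
  Tm[1:5e3, 2] <- Tm[1:5e3, 2] + b
  ie <- iterative_ebicow(panel_from_t(Tm), Psi = Psi)
  expect_equal(ie$state$U, 1L)
  expect_equal(length(ie$panel$labels), 2L)
  expect_equal(sum(ie$state$log$action == "accepted"), 1L)
  expect_equal(ie$state$log$pair[ie$state$log$action == "accepted"],
               "gwas1|gwas2")
  # coefficient bookkeeping maps 3 inputs to 2 outputs
  expect_equal(dim(ie$state$coef), c(2L, 3L))

  # no combinable structure: loop leaves the panel untouched
  Tm0 <- draw_mvn(3e4, diag(3), seed = 26)
  ie0 <- iterative_ebicow(panel_from_t(Tm0), Psi = diag(3))
  expect_equal(ie0$state$U, 0L)
  expect_equal(ie0$panel$t, panel_from_t(Tm0)$t)
})

test_that("near-collinear pairs are force-combined with the stable form", {
  set.seed(27)
  Psi <- exch(2, 0.8)          # psi^2 = 0.64 > 0.5
  Tm <- draw_mvn(3e4, Psi, seed = 27)
  ie <- iterative_ebicow(panel_from_t(Tm), Psi = Psi)
  expect_equal(ie$state$log$action, "forced")
  expect_equal(ie$state$log$variant, "hom")
  expect_equal(length(ie$panel$labels), 1L)
  # forced output is still standard normal under the null
  expect_lt(abs(mean(ie$panel$t[, 1]^2) - 1), 0.05)
})
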