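test_that("substitution effects and their inbreeding split are exact", {
  # no inbreeding: alpha reduces to a + (q - p) d
  ef <- locus_effects(p = 0.3, a = 1, d = 0.5, F = 0)
  expect_equal(ef$alpha_F, 0)
  expect_equal(ef$alpha, 1 + 0.4 * 0.5)
  # complete inbreeding: only homozygotes, alpha = a
  ef1 <- locus_effects(p = 0.3, a = 1, d = 0.5, F = 1)
  expect_equal(ef1$alpha, 1)
  expect_equal(ef1$alpha_noF + ef1$alpha_F, ef1$alpha)
  # symmetric frequencies kill the inbreeding-dependent part
  expect_equal(locus_effects(0.5, 2, -1, 0.7)$alpha_F, 0)
})

test_that("alpha = alpha_noF + alpha_F over random parameter draws", {
  set.seed(1)
  n <- 2000
  p <- runif(n, 0.01, 0.99)
  a <- rnorm(n)
  d <- rnorm(n)
  F <- runif(n)
  ef <- locus_effects(p, a, d, F)
  expect_lt(max(abs(ef$alpha - (ef$alpha_noF + ef$alpha_F))), 1e-12)
  # e = alpha (1 + F) by definition
  expect_lt(max(abs(ef$e - ef$alpha * (1 + F))), 1e-12)
})

test_that("genotype load values agree between gene-count and closed forms", {
  expect_equal(unname(load_values(0.3, 1, 0.5, 0)), c(0, 0, 0))
  expect_equal(unname(load_values(0.5, 1, 0.5, 0.8)), c(0, 0, 0))
  lv <- load_values(0.3, 1, 0.5, 1)
  expect_equal(unname(lv["i_A1A1"]), -0.28)
  # closed forms: -4 F/(1+F) q (q-p) d etc.
  p <- 0.17; q <- 1 - p; d <- -0.9; F <- 0.43
  lv2 <- load_values(p, a = 2, d = d, F = F)
  expect_equal(unname(lv2["i_A1A1"]), -4 * F / (1 + F) * q * (q - p) * d)
  expect_equal(unname(lv2["i_A1A2"]), -2 * F / (1 + F) * (q - p)^2 * d)
  expect_equal(unname(lv2["i_A2A2"]), 4 * F / (1 + F) * p * (q - p) * d)
})

test_that("locus moments match brute-force genotype enumeration", {
  # enumeration oracle: variance of the centered gene content times alpha_F
  # under Hardy-Weinberg class frequencies (the genic 2pq convention)
  brute <- function(p, a, d, F) {
    q <- 1 - p
    ef <- locus_effects(p, a, d, F)
    hw <- c(p^2, 2 * p * q, q^2)
    g <- c(2, 1, 0)
    load <- (g - 2 * p) * ef$alpha_F
    mu <- sum(hw * load)
    sum(hw * (load - mu)^2)
  }
  expect_equal(locus_moments(0.3, 1, 0.5, 0.2)$sigma_i2, brute(0.3, 1, 0.5, 0.2))
  expect_equal(locus_moments(0.3, 1, 0.5, 0.2)$sigma_i2, 1.86667e-3,
               tolerance = 1e-5)
  set.seed(2)
  for (i in 1:500) {
    p <- runif(1, 0.02, 0.98); a <- rnorm(1); d <- rnorm(1); F <- runif(1)
    m <- locus_moments(p, a, d, F)
    expect_equal(m$sigma_i2, brute(p, a, d, F), tolerance = 1e-12)
  }
})

test_that("moment signs, degeneracies and the F-free correlation hold", {
  m0 <- locus_moments(0.3, 1, 0.5, 0)
  expect_equal(m0$sigma_i2, 0)
  expect_equal(m0$sigma_ui, 0)
  # pure dominance: squared correlation is 1
  expect_equal(locus_moments(0.3, 0, 0.7, 0.4)$r2_ui, 1)
  # degenerate corner flagged, reported 0
  md <- locus_moments(0.5, 1, 0.5, 0.5)
  expect_false(md$r2_defined)
  expect_equal(md$r2_ui, 0)
  set.seed(3)
  for (i in 1:200) {
    p <- runif(1, 0.02, 0.98); a <- rnorm(1); d <- rnorm(1); F <- runif(1)
    m <- locus_moments(p, a, d, F)
    expect_lte(m$sigma_ui, 0)
    if (F > 0 && d != 0 && p != 0.5) expect_lt(m$sigma_ui, 0)
    # r2 does not depend on F
    expect_equal(m$r2_ui, locus_moments(p, a, d, 0.123)$r2_ui)
    # magnitude bound implied by the closed forms
    expect_lte(m$sigma_i2, m$sigma_u2 * 4 * F^2 / (1 + F)^2 + 1e-12)
  }
})

test_that("simulation recovers the substitution effect and load variance", {
  r <- empirical_check(p = 0.5, a = 1, d = 0.3, F = 0, n = 1e5, seed = 1)
  expect_true(r$ok_alpha)
  expect_equal(r$alpha, 1)  # at p = q, alpha = a
  r2 <- empirical_check(p = 0.3, a = 1, d = 0.5, F = 0.5, n = 2e5, seed = 2)
  expect_true(r2$ok_alpha)
  expect_true(r2$ok_sigma_i2)
  expect_equal(r2$alpha,
               with(locus_effects(0.3, 1, 0.5, 0.5), e / 1.5))
  # no dominance: no load
  r3 <- suppressWarnings(  # a zero-dominance locus fits exactly
    empirical_check(p = 0.4, a = 1.2, d = 0, F = 0.3, n = 1e5, seed = 3))
  expect_true(r3$ok_alpha)
  expect_equal(r3$sigma_i2, 0)
  expect_lt(r3$sigma_i2_hat, 1e-12)
  w <- capture_warnings(empirical_check(0.5, 1, 0, 0, n = 100, seed = 1))
  expect_true(any(grepl("unstable", w)))
})
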