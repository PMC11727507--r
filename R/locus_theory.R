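#' Single-locus substitution effects under non-random mating
#'
#' For a biallelic locus with allele A1 at frequency `p`, additive and
#' dominance biological effects `a` and `d` (genotypic values `a`, `d`, `-a`
#' for A1A1, A1A2, A2A2) and inbreeding coefficient `F`, computes the average
#' excess `e = a(1+F) + d(q-p)(1-F)`, the substitution effect
#' `alpha = e/(1+F)`, and its split into a no-inbreeding part
#' `alpha_noF = a + (q-p)d` and the inbreeding-dependent part
#' `alpha_F = -2 F/(1+F) (q-p) d`, with `alpha = alpha_noF + alpha_F`.
#'
#' @param p frequency of allele A1, in (0, 1).
#' @param a additive biological effect (trait units).
#' @param d dominance biological effect (trait units).
#' @param F inbreeding coefficient in `[0, 1]` (here a population-level
#'   departure from Hardy-Weinberg proportions).
#' @return a list with `e`, `alpha`, `alpha_noF`, `alpha_F` (all vectorized
#'   over the inputs).
#' @examples
#' locus_effects(p = 0.3, a = 1, d = 0.5, F = 0)$alpha  # 1.2
#' @export
locus_effects <- function(p, a, d, F) {
  stopifnot(all(p > 0 & p < 1), all(F >= 0 & F <= 1))
  q <- 1 - p
  e <- a * (1 + F) + d * (q - p) * (1 - F)
  alpha_noF <- a + (q - p) * d
  alpha_F <- -2 * F / (1 + F) * (q - p) * d
  list(e = e, alpha = e / (1 + F), alpha_noF = alpha_noF, alpha_F = alpha_F)
}

#' Single-locus inbreeding load values per genotype
#'
#' The inbreeding load of a genotype is its centered gene content
#' (`mu = 2p`) times the inbreeding-dependent substitution effect `alpha_F`:
#' `(2 - 2p) alpha_F`, `(1 - 2p) alpha_F`, `(-2p) alpha_F` for A1A1, A1A2,
#' A2A2 respectively.
#'
#' @inheritParams locus_effects
#' @return named numeric vector `c(i_A1A1, i_A1A2, i_A2A2)` (trait units).
#' @export
load_values <- function(p, a, d, F) {
  ef <- locus_effects(p, a, d, F)
  counts <- c(i_A1A1 = 2, i_A1A2 = 1, i_A2A2 = 0)
  vapply(counts, function(g) (g - 2 * p) * ef$alpha_F, numeric(1))
}

#' Single-locus variance components of the inbreeding load
#'
#' Closed-form second moments at one locus: the load variance
#' `sigma_i2 = 2pq alpha_F^2 = 8pq F^2/(1+F)^2 (q-p)^2 d^2`, the usual
#' additive variance `sigma_u2 = 2pq a^2 + 2pq (q-p)^2 d^2`, their covariance
#' `sigma_ui = -4pq F/(1+F) (q-p)^2 d^2` (always non-positive), and the
#' squared correlation `r2_ui`, which equals the dominance fraction
#' `2pq(q-p)^2 d^2 / sigma_u2` and is free of `F`. At degenerate corners
#' where `sigma_u2 * sigma_i2 = 0` the squared correlation is reported as 0
#' with `r2_defined = FALSE`.
#'
#' @inheritParams locus_effects
#' @return a list with `sigma_i2`, `sigma_u2`, `sigma_ui`, `r2_ui`,
#'   `r2_defined`.
#' @export
locus_moments <- function(p, a, d, F) {
  stopifnot(p > 0, p < 1, F >= 0, F <= 1)
  q <- 1 - p
  dom <- 2 * p * q * (q - p)^2 * d^2
  sigma_i2 <- 8 * p * q * F^2 / (1 + F)^2 * (q - p)^2 * d^2
  sigma_u2 <- 2 * p * q * a^2 + dom
  sigma_ui <- -4 * p * q * F / (1 + F) * (q - p)^2 * d^2
  defined <- sigma_u2 * sigma_i2 > 0
  r2 <- if (defined) dom / sigma_u2 else 0
  list(sigma_i2 = sigma_i2, sigma_u2 = sigma_u2, sigma_ui = sigma_ui,
       r2_ui = r2, r2_defined = defined)
}

#' Simulation check of the single-locus theory
#'
#' Draws `n` genotypes with inbred-population frequencies
#' `(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)`, assigns genotypic values
#' `(a, d, -a)`, and verifies that the least-squares regression of genotypic
#' value on gene content recovers the substitution effect `alpha = e/(1+F)`,
#' within `tol_se` standard errors. The load variance `sigma_i2 = 2pq
#' alpha_F^2` is defined against the Hardy-Weinberg gene-content variance
#' `2pq` (the genic convention of the closed forms), so it is checked on a
#' second sample drawn at Hardy-Weinberg proportions: the empirical variance
#' of the centered gene content times `alpha_F` must match
#' [locus_moments()].
#'
#' @inheritParams locus_effects
#' @param n sample size (>= 1e4 recommended; smaller values warn).
#' @param seed integer seed; the global RNG state is left untouched.
#' @param tol_se tolerance in standard errors (default 4).
#' @return a list with `alpha_hat`, `alpha`, `se_alpha`, `ok_alpha`,
#'   empirical and theoretical load moments with their flags, and `n`.
#' @export
empirical_check <- function(p, a, d, F, n = 1e5, seed = 1, tol_se = 4) {
  if (n < 1e4) warning("n < 1e4: estimates may be unstable")
  q <- 1 - p
  probs <- c(p^2 + F * p * q, 2 * p * q * (1 - F), q^2 + F * p * q)
  vals <- c(a, d, -a)
  ef <- locus_effects(p, a, d, F)
  mom <- locus_moments(p, a, d, F)
  draws <- with_seed(seed, {
    g <- sample(c(2, 1, 0), n, replace = TRUE, prob = probs)
    g_hw <- sample(c(2, 1, 0), n, replace = TRUE,
                   prob = c(p^2, 2 * p * q, q^2))
    list(g = g, g_hw = g_hw)
  })
  g <- draws$g
  y <- vals[3 - g]
  fit <- stats::lm(y ~ g)
  alpha_hat <- unname(stats::coef(fit)[2])
  se_alpha <- unname(sqrt(diag(stats::vcov(fit)))[2])
  # empirical load at Hardy-Weinberg proportions (genic convention)
  iload <- (draws$g_hw - 2 * p) * ef$alpha_F
  sigma_i2_hat <- mean(iload^2) - mean(iload)^2
  se_i2 <- stats::sd((iload - mean(iload))^2) / sqrt(n)
  list(
    alpha = ef$alpha, alpha_hat = alpha_hat, se_alpha = se_alpha,
    ok_alpha = abs(alpha_hat - ef$alpha) <= tol_se * se_alpha + 1e-8,
    sigma_i2 = mom$sigma_i2, sigma_i2_hat = sigma_i2_hat, se_sigma_i2 = se_i2,
    ok_sigma_i2 = abs(sigma_i2_hat - mom$sigma_i2) <= tol_se * se_i2 + 1e-12,
    n = n
  )
}

#' Tabulate single-locus theory quantities
#'
#' Convenience wrapper returning one row of all closed-form quantities for a
#' parameter combination; used by the `theory` pipeline subcommand.
#'
#' @inheritParams locus_effects
#' @return one-row `data.frame`.
#' @export
locus_table <- function(p, a, d, F) {
  ef <- locus_effects(p, a, d, F)
  lv <- load_values(p, a, d, F)
  mom <- locus_moments(p, a, d, F)
  data.frame(p = p, a = a, d = d, F = F,
             e = ef$e, alpha = ef$alpha, alpha_noF = ef$alpha_noF,
             alpha_F = ef$alpha_F,
             i_A1A1 = lv[["i_A1A1"]], i_A1A2 = lv[["i_A1A2"]],
             i_A2A2 = lv[["i_A2A2"]],
             sigma_i2 = mom$sigma_i2, sigma_u2 = mom$sigma_u2,
             sigma_ui = mom$sigma_ui, r2_ui = mom$r2_ui)
}
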