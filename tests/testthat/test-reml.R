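test_that("REML finds the grid-search optimum on toy data", {
  ds <- small_dataset(seed = 3)
  fit <- reml_fit(ds$ped, ds$F, NULL, ds$data, model = "RM",
                  opts = list(se = FALSE))
  expect_true(fit$converged)
  # coarse grid over the components: no grid point may beat the optimum
  grid <- expand.grid(sigma_u2 = c(100, 400, 900, 1600),
                      sigma_p2 = c(100, 400, 900),
                      sigma_e2 = c(400, 900, 1600, 2500))
  m2 <- apply(grid, 1, function(g)
    reml_loglik(ds$ped, ds$F, NULL, ds$data, as.list(g), "RM"))
  expect_lte(fit$minus2logL, min(m2) + 1e-6)
  # reported likelihood is consistent with direct evaluation at the estimates
  expect_equal(reml_loglik(ds$ped, ds$F, NULL, ds$data, fit$components, "RM"),
               fit$minus2logL, tolerance = 1e-6)
})

test_that("full-model fit reports components, solutions and load BLUPs", {
  ds <- small_dataset(seed = 5)
  fit <- suppressWarnings(
    reml_fit(ds$ped, ds$F, ds$design, ds$data, model = "FM"))
  expect_s3_class(fit, "inbload_fit")
  expect_length(fit$i_hat, nrow(ds$ped))
  expect_length(fit$u_hat, nrow(ds$ped))
  # load effects are predicted for animals with empty K columns too
  empty_cols <- setdiff(as.character(ds$ped$id),
                        unique(as.character(ds$partials$ancestor)))
  expect_true(all(is.finite(fit$i_hat[empty_cols])))
  expect_true(all(c("sigma_u2", "sigma_i2", "sigma_ui", "sigma_p2",
                    "sigma_e2") %in% names(fit$se)))
  expect_true(is.finite(fit$b_hat) && is.finite(fit$b_se))
  expect_equal(reml_loglik(ds$ped, ds$F, ds$design, ds$data, fit$components,
                           "FM"),
               fit$minus2logL, tolerance = 1e-5)
})

test_that("likelihood-ratio test follows the boundary-mixture convention", {
  # equal likelihoods
  lrt0 <- likelihood_ratio_test(100, 100)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)
  # published -2 logL pairs reproduce the printed statistic
  lrt <- likelihood_ratio_test(5379562.702, 5379715.675)
  expect_equal(lrt$statistic, 152.973, tolerance = 1e-9)
  # half-chi2 convention reproduces the printed p-value's magnitude
  p <- likelihood_ratio_test(0, 132.032)$p_value
  expect_equal(p, 7.4e-31, tolerance = 0.01)
  # nesting violations and clips
  expect_error(likelihood_ratio_test(10, 9), "nesting")
  expect_warning(lrtn <- likelihood_ratio_test(10, 10 - 1e-8), "clipped")
  expect_equal(lrtn$statistic, 0)
})

test_that("component summaries reproduce the derived report quantities", {
  s <- summarize_components(sigma_u2 = 1205.7, sigma_i2 = 12923.0,
                            sigma_ui = -460.1, b = -50.6,
                            trait_mean = 197.52)
  expect_equal(s$rescaled_load_variance, 129.23)
  expect_equal(s$r_ui, -0.12, tolerance = 0.04)
  expect_equal(s$depression_rate_pct, 0.26, tolerance = 0.02)
  s2 <- summarize_components(847.9, 11804.0, -289.0, b = -109.0,
                             trait_mean = 193.00)
  expect_equal(s2$rescaled_load_variance, 118.04)
  expect_equal(s2$depression_rate_pct, 0.56, tolerance = 0.02)
  # undefined correlation at zero load variance
  s0 <- summarize_components(800, 0, 0, b = -100, trait_mean = 200)
  expect_false(s0$r_defined)
  expect_true(is.na(s0$r_ui))
})

test_that("fit summaries combine predicted loads with overall depression", {
  ds <- small_dataset(seed = 5)
  fit <- suppressWarnings(
    reml_fit(ds$ped, ds$F, ds$design, ds$data, model = "FM",
             opts = list(se = FALSE)))
  s <- summarize_fit(fit, trait_mean = 193)
  expect_equal(s$total_effect, fit$i_hat + fit$b_hat)
  expect_gte(s$pct_positive_load, s$pct_positive_total)
  expect_equal(unname(s$i_hat_summary["mean"]), mean(fit$i_hat))
  # an animal with load +60 and depression -50 nets +10 per inbred descendant
  expect_equal(60 + summarize_components(1, 1, 0, -50, 197)$depression_at_F_ref / 0.10,
               10)
  rm_fit <- reml_fit(ds$ped, ds$F, NULL, ds$data, model = "RM",
                     opts = list(se = FALSE))
  expect_error(summarize_fit(rm_fit, 193), "full-model")
})
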