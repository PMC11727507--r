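test_that("pedigree simulation is deterministic and structurally sound", {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    sires_per_generation = 4, dams_per_generation = 8,
                    offspring_per_dam = 2)
  p1 <- simulate_pedigree(cfg, seed = 42)
  p2 <- simulate_pedigree(cfg, seed = 42)
  expect_identical(p1, p2)
  p3 <- simulate_pedigree(cfg, seed = 43)
  expect_false(identical(p1, p3))
  # one-generation configuration: founders only, all F = 0
  cfg0 <- sim_config(n_founders = 15, n_generations = 0)
  p0 <- simulate_pedigree(cfg0, seed = 1)
  expect_equal(nrow(p0), 15)
  expect_true(all(compute_inbreeding(p0) == 0))
})

test_that("grandparent avoidance lowers inbreeding versus random mating", {
  base <- list(n_founders = 40, n_generations = 5, sires_per_generation = 8,
               dams_per_generation = 25, offspring_per_dam = 2)
  diffs <- sapply(1:10, function(s) {
    pa <- simulate_pedigree(do.call(sim_config,
          c(base, mating_policy = "avoid_common_grandparents")), seed = s)
    pr <- simulate_pedigree(do.call(sim_config,
          c(base, mating_policy = "random")), seed = s)
    mean(compute_inbreeding(pa)) - mean(compute_inbreeding(pr))
  })
  # paired sign test across seeds
  expect_lt(binom.test(sum(diffs < 0), length(diffs),
                       alternative = "greater")$p.value, 0.05)
})

test_that("avoided matings leave no shallow inbreeding loops", {
  cfg <- sim_config(n_founders = 80, n_generations = 5,
                    sires_per_generation = 25, dams_per_generation = 30,
                    offspring_per_dam = 2)
  ped <- simulate_pedigree(cfg, seed = 9)
  expect_equal(attr(ped, "n_fallback"), 0L)
  pp <- compute_partial_inbreeding(ped)
  # closest permitted loops are deeper than shared grandparents, so no
  # partial coefficient can reach the half-sib/grandparent level 0.125
  if (nrow(pp)) expect_true(all(pp$partial_f < 0.125))
})

test_that("genetic effects have the prescribed bivariate pedigree covariance", {
  G <- matrix(c(800, -300, -300, 10000), 2, 2)
  # founders: direct N(0, G) draws
  ped2 <- ped_founders(2)
  nrep <- 4000
  draws <- sapply(1:nrep, function(r)
    simulate_genetic_effects(ped2, G_true = G, seed = r)[1, ])
  emp <- cov(t(draws))
  se <- sqrt((G[1, 1] * G[2, 2] + G^2) / nrep)
  expect_true(all(abs(emp - G) < 4 * se))
  # trio: cov(u_child, u_parent) = sigma_u2 / 2
  ped3 <- pedigree(1:3, c(0, 0, 1), c(0, 0, 2))
  us <- sapply(1:nrep, function(r) {
    e <- simulate_genetic_effects(ped3, G_true = G, seed = 10000 + r)
    c(e[1, "u"], e[3, "u"])
  })
  expect_lt(abs(cov(us[1, ], us[2, ]) - G[1, 1] / 2),
            4 * G[1, 1] / sqrt(nrep))
  # zero G: all effects zero
  expect_true(all(simulate_genetic_effects(ped3, G_true = matrix(0, 2, 2),
                                           seed = 1) == 0))
})

test_that("phenotypes follow the generative equation exactly when noiseless", {
  cfg <- sim_config(n_founders = 12, n_generations = 3,
                    sires_per_generation = 3, dams_per_generation = 6,
                    offspring_per_dam = 2, mating_policy = "random",
                    sigma_u2 = 0, sigma_i2 = 0, sigma_ui = 0, sigma_p2 = 0,
                    sigma_e2 = 0, b = 0, n_fyp = 1, fyp_sd = 0)
  ds <- simulate_dataset(cfg, seed = 2)
  expect_true(all(ds$data$y == cfg$trait_mean))
  # pure depression: records shift by f * b
  cfg_b <- sim_config(n_founders = 12, n_generations = 3,
                      sires_per_generation = 3, dams_per_generation = 6,
                      offspring_per_dam = 2, mating_policy = "random",
                      sigma_u2 = 0, sigma_i2 = 0, sigma_ui = 0, sigma_p2 = 0,
                      sigma_e2 = 0, b = -110.4, n_fyp = 1, fyp_sd = 0)
  ds_b <- simulate_dataset(cfg_b, seed = 2)
  expect_equal(ds_b$data$y, cfg_b$trait_mean - 110.4 * ds_b$data$f)
  # an animal at f = 0.10 would lose 11.04 in every record
  expect_equal(cfg_b$trait_mean + cfg_b$b * 0.10, cfg_b$trait_mean - 11.04)
  # residual-only variance matches sigma_e2
  cfg_e <- sim_config(n_founders = 40, n_generations = 2,
                      sires_per_generation = 8, dams_per_generation = 20,
                      offspring_per_dam = 2, sigma_u2 = 0, sigma_i2 = 0,
                      sigma_ui = 0, sigma_p2 = 0, sigma_e2 = 900, b = 0,
                      n_fyp = 1, fyp_sd = 0, records_per_female = 4)
  ds_e <- simulate_dataset(cfg_e, seed = 3)
  expect_lt(abs(var(ds_e$data$y) - 900) / 900, 0.2)
})

test_that("simulated phenotype covariance matches the model-implied V", {
  cfg <- sim_config(n_founders = 8, n_generations = 3,
                    sires_per_generation = 3, dams_per_generation = 5,
                    offspring_per_dam = 2, n_fyp = 1, fyp_sd = 0,
                    mating_policy = "random", records_per_female = 2)
  ped <- simulate_pedigree(cfg, seed = 5)
  F <- compute_inbreeding(ped)
  design <- build_K(compute_partial_inbreeding(ped, F = F),
                    build_parent_matrix(ped), threshold = 0)
  G <- matrix(c(cfg$sigma_u2, cfg$sigma_ui, cfg$sigma_ui, cfg$sigma_i2), 2, 2)
  nrep <- 2000
  ys <- sapply(seq_len(nrep), function(r) {
    eff <- simulate_genetic_effects(ped, F, G, seed = 10000 + r)
    simulate_phenotypes(ped, F, design, eff, cfg, seed = 50000 + r)$y
  })
  d1 <- simulate_phenotypes(ped, F, design,
                            simulate_genetic_effects(ped, F, G, seed = 1),
                            cfg, seed = 1)
  dd <- dense_design(ped, design, d1, "FM")
  V <- dense_V(ped, dd, cfg[c("sigma_u2", "sigma_i2", "sigma_ui",
                              "sigma_p2", "sigma_e2")], "FM")
  emp <- cov(t(ys))
  z <- (emp - V) / (sqrt(outer(diag(V), diag(V)) + V^2) / sqrt(nrep))
  expect_lt(max(abs(z)), 5)
})

test_that("recovery experiments collect estimates, coverage and tests", {
  cfg <- sim_config(n_founders = 14, n_generations = 4,
                    sires_per_generation = 3, dams_per_generation = 8,
                    offspring_per_dam = 2, n_fyp = 3,
                    mating_policy = "random")
  rec <- recovery_experiment(cfg, n_replicates = 2, seed = 4,
                             reml_opts = list(reltol = 1e-8, restarts = 0))
  expect_equal(nrow(rec), 2)
  expect_true(all(c("sigma_u2_est", "sigma_u2_se", "sigma_u2_covered",
                    "b_est", "lrt", "lrt_p") %in% names(rec)))
  expect_true(all(is.finite(rec$sigma_u2_est)))
  truth <- attr(rec, "truth")
  expect_equal(unname(truth["b"]), cfg$b)
})
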