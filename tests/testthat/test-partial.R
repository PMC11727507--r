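test_that("partial coefficients match the worked decompositions", {
  # dam-son: all inbreeding due to the founder dam
  pp <- compute_partial_inbreeding(ped_dam_son())
  expect_equal(nrow(pp), 1)
  expect_equal(pp$descendant, 4)
  expect_equal(pp$ancestor, 1)
  expect_equal(pp$partial_f, 0.25)

  # full sibs: split evenly over the two founders, none on the parents
  pp <- compute_partial_inbreeding(ped_full_sib())
  expect_equal(pp$partial_f, c(0.125, 0.125))
  expect_setequal(pp$ancestor, c(1, 2))
  expect_false(any(pp$ancestor %in% c(3, 4)))

  # non-founder ancestor contributes through its Mendelian sampling
  pp <- compute_partial_inbreeding(ped_grandparents())
  expect_equal(pp$partial_f[pp$ancestor == 3], 0.125)
  expect_equal(pp$partial_f[pp$ancestor == 1], 0.0625)
  expect_equal(pp$partial_f[pp$ancestor == 2], 0.0625)
  expect_equal(sum(pp$partial_f), 0.25)

  # no inbreeding -> empty set
  expect_equal(nrow(compute_partial_inbreeding(ped_founders(4))), 0)
})

test_that("partial coefficients sum to total inbreeding", {
  for (s in 1:25) {
    ped <- random_pedigree(60, seed = 100 + s)
    F <- compute_inbreeding(ped)
    pp <- compute_partial_inbreeding(ped, F = F)
    sums <- tapply(pp$partial_f, pp$descendant, sum)
    expect_true(all(abs(F[names(sums)] - sums) < 1e-10))
    # animals not in the triplets must have F = 0
    rest <- setdiff(names(F)[F > 0], names(sums))
    expect_length(rest, 0)
    expect_true(all(pp$partial_f > 0 & pp$partial_f <= F[as.character(pp$descendant)] + 1e-12))
  }
})

test_that("screened sweep equals the unrestricted dense per-ancestor sweep", {
  for (s in c(2, 4, 8)) {
    ped <- random_pedigree(30, seed = s)
    F <- compute_inbreeding(ped)
    phi <- mendelian_variance(ped, F)
    oracle <- partials_dense_oracle(ped, phi)
    pp <- compute_partial_inbreeding(ped, phi = phi, F = F)
    got <- matrix(0, nrow(ped), nrow(ped), dimnames = dimnames(oracle))
    if (nrow(pp)) {
      got[cbind(match(pp$descendant, ped$id), match(pp$ancestor, ped$id))] <-
        pp$partial_f
    }
    expect_lt(max(abs(got - oracle)), 1e-12)
  }
})

test_that("decomposition matches gene-dropping Monte Carlo", {
  ped <- random_pedigree(12, seed = 4)  # includes inbred chain ancestors
  pp <- compute_partial_inbreeding(ped)
  gd <- gene_drop_partials(ped, nrep = 2e5, seed = 9)
  idx <- cbind(match(pp$descendant, ped$id), match(pp$ancestor, ped$id))
  se <- sqrt(pmax(pp$partial_f * (1 - pp$partial_f), 1e-9) / gd$nrep)
  expect_true(all(abs(gd$partial_hat[idx] - pp$partial_f) < 3 * se))
  # no Monte Carlo mass on pairs the decomposition calls zero
  stray <- gd$partial_hat
  stray[idx] <- 0
  expect_true(all(stray <= 3 * sqrt(0.25 / gd$nrep)))
})

test_that("inbreeding summaries report the decomposition structure", {
  ped <- ped_dam_son()
  F <- compute_inbreeding(ped)
  s <- summarize_inbreeding(F, compute_partial_inbreeding(ped))
  tab <- setNames(s$table$value, s$table$key)
  expect_equal(unname(tab["n_partial_coefficients"]), 1)
  expect_equal(unname(tab["max_partial_f"]), 0.25)
  expect_equal(unname(tab["n_ancestors_involved"]), 1)
  expect_equal(unname(tab["n_founder_ancestors"]), 1)
  expect_equal(unname(tab["pct_inbred"]), 25)

  s2 <- summarize_inbreeding(compute_inbreeding(ped_full_sib()),
                             compute_partial_inbreeding(ped_full_sib()))
  tab2 <- setNames(s2$table$value, s2$table$key)
  expect_equal(unname(tab2["n_partial_coefficients"]), 2)
  expect_equal(unname(tab2["n_founder_ancestors"]), 2)

  s0 <- summarize_inbreeding(compute_inbreeding(ped_founders(3)),
                             compute_partial_inbreeding(ped_founders(3)))
  tab0 <- setNames(s0$table$value, s0$table$key)
  expect_equal(unname(tab0["pct_inbred"]), 0)
  expect_equal(unname(tab0["n_partial_coefficients"]), 0)
})

test_that("partial coefficients export at full precision", {
  pp <- compute_partial_inbreeding(ped_grandparents())
  f <- withr::local_tempfile(fileext = ".txt")
  write_partials(pp, f)
  back <- read.table(f, header = TRUE)
  expect_equal(names(back), c("descendant", "ancestor", "partial_f"))
  expect_equal(back$partial_f, pp$partial_f, tolerance = 1e-15)
})
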