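# Toy pedigrees used across tests ------------------------------------------

# dam-son mating: A, B founders; C = A x B; D = A x C  -> F_D = 0.25
ped_dam_son <- function() pedigree(1:4, c(0, 0, 1, 1), c(0, 0, 2, 3))

# full sibs: E = C x D with C, D = A x B  -> F_E = 0.25
ped_full_sib <- function() pedigree(1:5, c(0, 0, 1, 1, 3), c(0, 0, 2, 2, 4))

# G1, G2 founders; A = G1 x G2; B founder; C = A x B; D = A x C
ped_grandparents <- function() pedigree(1:6, c(0, 0, 1, 0, 3, 3),
                                        c(0, 0, 2, 0, 4, 5))

# founders only
ped_founders <- function(n = 3) pedigree(seq_len(n), rep(0, n), rep(0, n))

# Random valid pedigree, independent of the package's simulator.
# Animals are added in order; each non-founder picks parents among earlier
# animals (possibly one unknown), so loops of all depths arise.
random_pedigree <- function(n, seed, p_founder = 0.25, p_one_parent = 0.15) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (j in seq_len(n)) {
    if (j <= 2 || runif(1) < p_founder) next
    s <- sample.int(j - 1L, 1L)
    d <- sample.int(j - 1L, 1L)
    while (d == s) d <- sample.int(j - 1L, 1L)
    if (runif(1) < p_one_parent) d <- 0L
    sire[j] <- s
    dam[j] <- d
  }
  pedigree(seq_len(n), sire, dam)
}

# small phenotype-bearing dataset for mixed-model tests
small_dataset <- function(seed = 7, n_fyp = 4) {
  cfg <- sim_config(n_founders = 12, n_generations = 4,
                    sires_per_generation = 3, dams_per_generation = 8,
                    offspring_per_dam = 2, n_fyp = n_fyp,
                    mating_policy = "random")
  simulate_dataset(cfg, seed = seed)
}
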