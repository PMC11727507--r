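#' Simulation configuration
#'
#' Bundles the parameters of the synthetic pedigree/phenotype generator.
#' Defaults emulate a closed dairy-sheep nucleus: overlapping generations,
#' matings that avoid pairs sharing a grandparent, low mean inbreeding,
#' repeated lactation records on females only, flock-year-parity fixed
#' effects, and genetic true values drawn under the bivariate
#' (additive, load) model with the load expressed per fully inbred
#' descendant (hence a variance roughly an order of magnitude above the
#' additive one).
#'
#' @param n_founders number of founder animals.
#' @param n_generations number of discrete birth cohorts after the founders.
#' @param sires_per_generation,dams_per_generation parents selected per
#'   cohort; candidates come from the two preceding cohorts (overlap).
#' @param offspring_per_dam litter size per dam and cohort.
#' @param mating_policy `"avoid_common_grandparents"` (default) or
#'   `"random"`.
#' @param sigma_u2,sigma_i2,sigma_ui,sigma_p2,sigma_e2 true variance
#'   components (trait units squared).
#' @param b true inbreeding-depression coefficient (trait units per unit
#'   inbreeding).
#' @param trait_mean overall trait mean.
#' @param n_fyp number of flock-year-parity classes.
#' @param fyp_sd standard deviation of the fixed class effects.
#' @param records_per_female records per phenotyped female.
#' @param female_ratio probability an offspring is female.
#' @param threshold `K` threshold used when *fitting*; phenotype generation
#'   always uses the exact (threshold 0) design.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 80, n_generations = 8,
                       sires_per_generation = 25, dams_per_generation = 150,
                       offspring_per_dam = 2,
                       mating_policy = c("avoid_common_grandparents", "random"),
                       sigma_u2 = 800, sigma_i2 = 10000, sigma_ui = -300,
                       sigma_p2 = 400, sigma_e2 = 1300, b = -110,
                       trait_mean = 193, n_fyp = 30, fyp_sd = 20,
                       records_per_female = 2, female_ratio = 0.5,
                       threshold = 0) {
  mating_policy <- match.arg(mating_policy)
  G <- matrix(c(sigma_u2, sigma_ui, sigma_ui, sigma_i2), 2, 2)
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values < 0)) {
    stop("true G = [[sigma_u2, sigma_ui], [sigma_ui, sigma_i2]] must be PSD")
  }
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              sires_per_generation = sires_per_generation,
              dams_per_generation = dams_per_generation,
              offspring_per_dam = offspring_per_dam,
              mating_policy = mating_policy,
              sigma_u2 = sigma_u2, sigma_i2 = sigma_i2, sigma_ui = sigma_ui,
              sigma_p2 = sigma_p2, sigma_e2 = sigma_e2, b = b,
              trait_mean = trait_mean, n_fyp = n_fyp, fyp_sd = fyp_sd,
              records_per_female = records_per_female,
              female_ratio = female_ratio, threshold = threshold)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an overlapping-generation pedigree
#'
#' Generates a pedigree under the configured mating policy. Under
#' `"avoid_common_grandparents"` no mated pair shares a grandparent; when no
#' valid sire exists for a dam the pair falls back to a random mate and the
#' number of fallbacks is recorded in attribute `"n_fallback"`. Parents are
#' drawn from the two preceding cohorts, giving overlapping generations.
#' Deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a [pedigree] with `year` (cohort) and `sex` codes.
#' @export
simulate_pedigree <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    id <- seq_len(cfg$n_founders)
    sire <- dam <- rep(0L, cfg$n_founders)
    year <- rep(0L, cfg$n_founders)
    sex <- rep(c("M", "F"), length.out = cfg$n_founders)
    grandparents <- function(a) {
      gp <- c(sire[sire[a]], dam[sire[a]], sire[dam[a]], dam[dam[a]])
      gp[!is.na(gp) & gp != 0L]
    }
    n_fallback <- 0L
    if (cfg$n_generations > 0) for (g in seq_len(cfg$n_generations)) {
      pool <- which(year >= g - 2L & year <= g - 1L |
                    (g == 1L & year == 0L))
      males <- pool[sex[pool] == "M"]
      females <- pool[sex[pool] == "F"]
      if (!length(males) || !length(females)) {
        stop("infeasible configuration: no candidate parents in cohort ", g)
      }
      ns <- min(cfg$sires_per_generation, length(males))
      nd <- min(cfg$dams_per_generation, length(females))
      sires_g <- sample(males, ns)
      dams_g <- sample(females, nd)
      for (dm in dams_g) {
        mate <- NA_integer_
        if (cfg$mating_policy == "avoid_common_grandparents") {
          gpd <- c(grandparents(dm), sire[dm], dam[dm], dm)
          gpd <- gpd[gpd != 0L]
          ok <- sires_g[vapply(sires_g, function(s) {
            gps <- c(grandparents(s), sire[s], dam[s], s)
            gps <- gps[gps != 0L]
            length(intersect(gpd, gps)) == 0L
          }, logical(1))]
          if (length(ok)) {
            mate <- if (length(ok) == 1L) ok else sample(ok, 1L)
          } else {
            n_fallback <- n_fallback + 1L
          }
        }
        if (is.na(mate)) {
          mate <- if (length(sires_g) == 1L) sires_g else sample(sires_g, 1L)
        }
        for (o in seq_len(cfg$offspring_per_dam)) {
          id <- c(id, length(id) + 1L)
          sire <- c(sire, mate)
          dam <- c(dam, dm)
          year <- c(year, g)
          sex <- c(sex, if (stats::runif(1) < cfg$female_ratio) "F" else "M")
        }
      }
    }
    ped <- pedigree(id, sire, dam, year = year, sex = sex)
    attr(ped, "n_fallback") <- n_fallback
    ped
  })
}

#' Simulate true additive and load effects
#'
#' Draws the bivariate true values `(u, i)` per animal with covariance
#' `G (x) A` exactly in distribution, by the pedigree recursion: founder
#' effects are `N(0, G)`; a non-founder is the mean of its known parents
#' plus a Mendelian-sampling residual with covariance `m_j G`, where `m_j`
#' is the animal's Mendelian sampling variance. This scales linearly with
#' pedigree size, with no dense Cholesky of `G (x) A`.
#'
#' @param ped a [pedigree].
#' @param F inbreeding coefficients; computed if omitted.
#' @param G_true 2x2 true genetic covariance matrix (PSD).
#' @param seed integer seed.
#' @return an `n x 2` matrix with columns `u`, `i` and rownames = animal ids.
#' @export
simulate_genetic_effects <- function(ped, F = NULL, G_true, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(F)) F <- compute_inbreeding(ped)
  G_true <- as.matrix(G_true)
  stopifnot(nrow(G_true) == 2, ncol(G_true) == 2)
  ev <- eigen(G_true, symmetric = TRUE)
  if (any(ev$values < -1e-8 * sum(abs(ev$values)))) stop("G_true must be PSD")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  n <- nrow(ped)
  m <- unname(mendelian_variance(ped, F))
  with_seed(seed, {
    R <- matrix(stats::rnorm(2 * n), n, 2) %*% L * sqrt(m)
    eff <- matrix(0, n, 2, dimnames = list(ped$id, c("u", "i")))
    sr <- ped$sire_row; dr <- ped$dam_row
    for (j in seq_len(n)) {
      v <- R[j, ]
      if (!is.na(sr[j])) v <- v + 0.5 * eff[sr[j], ]
      if (!is.na(dr[j])) v <- v + 0.5 * eff[dr[j], ]
      eff[j, ] <- v
    }
    eff
  })
}

#' Simulate phenotypes under the load model
#'
#' Generates repeated records for females under the generative model
#' `y = mu + fyp + f b + u + (K i) + p + e` with a permanent-environment
#' effect drawn once per animal. The supplied design must be exact
#' (`threshold = 0`) for the generative model to hold.
#'
#' @param ped a [pedigree].
#' @param F inbreeding coefficients; computed if omitted.
#' @param design a `"load_design"` built with threshold 0.
#' @param effects matrix of true `(u, i)` from [simulate_genetic_effects()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a `data.frame` with columns `animal_id`, `fyp`, `f`, `y`; the
#'   per-record truth components (`u_true`, `ki_true`, `p_true`) are
#'   attached as attribute `"truth"` for validation.
#' @export
simulate_phenotypes <- function(ped, F = NULL, design, effects, cfg, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (is.null(F)) F <- compute_inbreeding(ped)
  if (!is.null(design) && design$threshold != 0) {
    warning("phenotype generation expects an exact design (threshold 0)")
  }
  n <- nrow(ped)
  ki <- if (is.null(design)) numeric(n) else
    as.numeric(design$K %*% effects[, "i"])
  females <- which(!is.na(ped$sex) & ped$sex == "F" & ped$year > 0)
  if (!length(females)) females <- which(!is.na(ped$sex) & ped$sex == "F")
  with_seed(seed, {
    fyp_eff <- stats::rnorm(cfg$n_fyp, 0, cfg$fyp_sd)
    p_eff <- stats::rnorm(n, 0, sqrt(cfg$sigma_p2))
    rows <- rep(females, each = cfg$records_per_female)
    nrec <- length(rows)
    fyp <- sample.int(cfg$n_fyp, nrec, replace = TRUE)
    e <- stats::rnorm(nrec, 0, sqrt(cfg$sigma_e2))
    y <- cfg$trait_mean + fyp_eff[fyp] + F[rows] * cfg$b +
      effects[rows, "u"] + ki[rows] + p_eff[rows] + e
    out <- data.frame(animal_id = ped$id[rows], fyp = fyp,
                      f = unname(F[rows]), y = unname(y))
    attr(out, "truth") <- data.frame(
      u_true = unname(effects[rows, "u"]),
      ki_true = unname(ki[rows]), p_true = unname(p_eff[rows]))
    out
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [compute_inbreeding()], [compute_partial_inbreeding()], [build_K()]
#' (exact, threshold 0, for generation), [simulate_genetic_effects()] and
#' [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; sub-seeds for the pedigree, effects and
#'   records are derived from it.
#' @return a list with `ped`, `F`, `partials`, `design` (exact),
#'   `fit_design` (thresholded at `cfg$threshold` if nonzero, else the same
#'   object), `effects`, `data`, `cfg`, `seed`.
#' @export
simulate_dataset <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- simulate_pedigree(cfg, seed = derive_seed(seed, 1))
  F <- compute_inbreeding(ped)
  partials <- compute_partial_inbreeding(ped, F = F)
  P <- build_parent_matrix(ped)
  design <- build_K(partials, P, threshold = 0)
  fit_design <- if (cfg$threshold > 0) {
    build_K(partials, P, threshold = cfg$threshold)
  } else design
  G_true <- matrix(c(cfg$sigma_u2, cfg$sigma_ui, cfg$sigma_ui, cfg$sigma_i2),
                   2, 2)
  effects <- if (all(G_true == 0)) {
    matrix(0, nrow(ped), 2, dimnames = list(ped$id, c("u", "i")))
  } else {
    simulate_genetic_effects(ped, F, G_true, seed = derive_seed(seed, 2))
  }
  data <- simulate_phenotypes(ped, F, design, effects, cfg,
                              seed = derive_seed(seed, 3))
  list(ped = ped, F = F, partials = partials, design = design,
       fit_design = fit_design, effects = effects, data = data,
       cfg = cfg, seed = seed)
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline end to end on simulated data: per replicate,
#' simulate a dataset, fit RM and FM by REML, and record variance-component
#' estimates with their standard errors, +/- 2 SE coverage of the truth,
#' the depression coefficient and the likelihood-ratio test. Non-converged
#' replicates are recorded, not fatal.
#'
#' @param cfg a [sim_config()].
#' @param n_replicates number of replicates.
#' @param seed base seed; each replicate uses a derived sub-seed.
#' @param fit_fm also fit the full model (default TRUE); with `FALSE` only
#'   the reduced model is fitted and LRT columns are `NA`.
#' @param se compute standard errors (needed for coverage; default TRUE).
#' @param reml_opts extra options passed to [reml_fit()].
#' @return a `data.frame` with one row per replicate: estimates, SEs,
#'   coverage flags, `lrt`, `lrt_p`, convergence flags; truth values are
#'   attached as attribute `"truth"` and a summary as attribute
#'   `"coverage"`.
#' @export
recovery_experiment <- function(cfg, n_replicates = 20, seed = 1,
                                fit_fm = TRUE, se = TRUE, reml_opts = list()) {
  stopifnot(inherits(cfg, "sim_config"))
  pars <- c("sigma_u2", "sigma_i2", "sigma_ui", "sigma_p2", "sigma_e2")
  truth <- c(unlist(cfg[pars]), b = cfg$b)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ds <- simulate_dataset(cfg, seed = derive_seed(seed, 100 + r))
    opts <- utils::modifyList(list(se = se), reml_opts)
    row <- list(replicate = r)
    rm_fit <- tryCatch(
      reml_fit(ds$ped, ds$F, NULL, ds$data, model = "RM", opts = opts),
      error = function(e) NULL)
    # anchor the FM start at the RM optimum so the nested model is never
    # left below the reduced one by early stopping
    fm_start <- if (!is.null(rm_fit)) {
      list(sigma_u2 = rm_fit$components$sigma_u2,
           sigma_p2 = rm_fit$components$sigma_p2,
           sigma_e2 = rm_fit$components$sigma_e2)
    } else NULL
    fm_obj <- if (fit_fm) tryCatch(
      suppressWarnings(
        reml_fit(ds$ped, ds$F, ds$fit_design, ds$data, model = "FM",
                 start = fm_start, opts = opts)),
      error = function(e) NULL) else NULL
    row$rm_converged <- !is.null(rm_fit) && rm_fit$converged
    row$fm_converged <- !is.null(fm_obj) && fm_obj$converged
    src <- if (fit_fm) fm_obj else rm_fit
    for (p in pars) {
      est <- if (!is.null(src)) src$components[[p]] else NA_real_
      sev <- if (!is.null(src) && !is.null(src$se)) src$se[[p]] else NA_real_
      row[[paste0(p, "_est")]] <- est
      row[[paste0(p, "_se")]] <- sev
      row[[paste0(p, "_covered")]] <-
        if (is.na(est) || is.na(sev)) NA else abs(est - truth[[p]]) <= 2 * sev
    }
    row$b_est <- if (!is.null(src)) src$b_hat else NA_real_
    row$b_se <- if (!is.null(src)) src$b_se else NA_real_
    row$b_covered <- if (!is.null(src) && !is.na(src$b_se)) {
      abs(src$b_hat - cfg$b) <= 2 * src$b_se
    } else NA
    if (fit_fm && !is.null(fm_obj) && !is.null(rm_fit)) {
      lrt <- tryCatch(suppressWarnings(likelihood_ratio_test(fm_obj, rm_fit)),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_))
      row$lrt <- lrt$statistic
      row$lrt_p <- lrt$p_value
    } else {
      row$lrt <- NA_real_
      row$lrt_p <- NA_real_
    }
    rows[[r]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  cov_cols <- grep("_covered$", names(out), value = TRUE)
  attr(out, "coverage") <- vapply(out[cov_cols],
                                  function(z) mean(z, na.rm = TRUE),
                                  numeric(1))
  out
}
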