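#' Run a pipeline stage
#'
#' Single entry point behind the command-line script: dispatches on a
#' subcommand and writes plain-text artifacts plus a machine-readable JSON
#' run manifest (inputs, seed, checksums) into the output directory.
#'
#' Subcommands:
#' \describe{
#'   \item{decompose}{read a pedigree file; write inbreeding coefficients,
#'     partial coefficients, the K matrix and a summary table.}
#'   \item{fit}{read pedigree + phenotype CSV; fit RM or FM by REML; write
#'     the variance-component table and per-animal solutions.}
#'   \item{compare}{fit both models and write an LRT table.}
#'   \item{simulate}{generate a synthetic dataset and write its files.}
#'   \item{theory}{write the single-locus theory table for given
#'     parameters.}
#'   \item{recover}{run a small parameter-recovery experiment.}
#' }
#'
#' @param config a named list: `subcommand`, `out_dir`, and
#'   subcommand-specific entries (`pedigree`, `phenotypes`, `model`,
#'   `threshold`, `seed`, `p`, `a`, `d`, `F`, `n_replicates`, `cfg`, ...).
#' @return invisibly, a list of written file paths.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand
  if (is.null(sub) || !sub %in% c("decompose", "fit", "compare", "simulate",
                                  "theory", "recover")) {
    stop("unknown or missing subcommand: ", if (is.null(sub)) "<none>" else sub)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  threshold <- if (is.null(config$threshold)) 0.01 else
    as.numeric(config$threshold)
  written <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    written <<- c(written, path)
    path
  }

  if (sub == "decompose") {
    ped <- read_pedigree(config$pedigree)
    F <- compute_inbreeding(ped)
    partials <- compute_partial_inbreeding(ped, F = F)
    design <- build_K(partials, build_parent_matrix(ped), threshold)
    utils::write.table(data.frame(animal = ped$id, F = F),
                       emit("inbreeding.txt"), row.names = FALSE,
                       quote = FALSE)
    write_partials(partials, emit("partials.txt"))
    write_K(design, emit("K.txt"))
    s <- summarize_inbreeding(F, partials)
    utils::write.table(s$table, emit("summary.txt"), row.names = FALSE,
                       quote = FALSE)
  } else if (sub %in% c("fit", "compare")) {
    ped <- read_pedigree(config$pedigree)
    data <- utils::read.csv(config$phenotypes)
    F <- compute_inbreeding(ped)
    design <- NULL
    model <- if (is.null(config$model)) "FM" else config$model
    if (sub == "compare" || model == "FM") {
      partials <- compute_partial_inbreeding(ped, F = F)
      design <- build_K(partials, build_parent_matrix(ped), threshold)
    }
    if (sub == "fit") {
      fit <- reml_fit(ped, F, design, data, model = model)
      .write_fit(fit, out_dir, emit)
    } else {
      fit_rm <- reml_fit(ped, F, NULL, data, model = "RM")
      fit_fm <- reml_fit(ped, F, design, data, model = "FM")
      .write_fit(fit_fm, out_dir, emit)
      lrt <- likelihood_ratio_test(fit_fm, fit_rm)
      utils::write.csv(data.frame(
        minus2logL_FM = fit_fm$minus2logL, minus2logL_RM = fit_rm$minus2logL,
        statistic = lrt$statistic, p_value = lrt$p_value),
        emit("lrt.csv"), row.names = FALSE)
    }
  } else if (sub == "simulate") {
    cfg <- do.call(sim_config, if (is.null(config$cfg)) list() else config$cfg)
    ds <- simulate_dataset(cfg, seed = seed)
    write_pedigree(ds$ped, emit("pedigree.txt"))
    utils::write.csv(ds$data[c("animal_id", "fyp", "f", "y")],
                     emit("phenotypes.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(animal_id = ds$ped$id, u_true = ds$effects[, "u"],
                 i_true = ds$effects[, "i"], F = ds$F),
      emit("truth.csv"), row.names = FALSE)
  } else if (sub == "theory") {
    grid <- locus_table(p = as.numeric(config$p), a = as.numeric(config$a),
                        d = as.numeric(config$d), F = as.numeric(config$F))
    utils::write.csv(grid, emit("theory.csv"), row.names = FALSE)
  } else if (sub == "recover") {
    cfg <- do.call(sim_config, if (is.null(config$cfg)) list() else config$cfg)
    nrep <- if (is.null(config$n_replicates)) 5L else
      as.integer(config$n_replicates)
    rec <- recovery_experiment(cfg, n_replicates = nrep, seed = seed)
    utils::write.csv(rec, emit("recovery.csv"), row.names = FALSE)
  }

  manifest <- list(
    subcommand = sub,
    seed = seed,
    threshold = threshold,
    inputs = lapply(
      Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
             config[c("pedigree", "phenotypes")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p))),
    package_version = as.character(utils::packageVersion("inbload")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(written, file.path(out_dir, "manifest.json")))
}

.write_fit <- function(fit, out_dir, emit) {
  cmp <- fit$components
  se <- fit$se
  getse <- function(nm) if (is.null(se) || is.null(se[[nm]])) NA_real_ else se[[nm]]
  utils::write.csv(data.frame(
    model = fit$model,
    sigma_u2 = cmp$sigma_u2, sigma_u2_se = getse("sigma_u2"),
    sigma_i2 = cmp$sigma_i2, sigma_i2_se = getse("sigma_i2"),
    sigma_ui = cmp$sigma_ui, sigma_ui_se = getse("sigma_ui"),
    sigma_p2 = cmp$sigma_p2, sigma_p2_se = getse("sigma_p2"),
    sigma_e2 = cmp$sigma_e2, sigma_e2_se = getse("sigma_e2"),
    b = fit$b_hat, b_se = fit$b_se,
    minus2logL = fit$minus2logL, converged = fit$converged),
    emit("components.csv"), row.names = FALSE)
  sol <- data.frame(animal_id = names(fit$u_hat), u_hat = fit$u_hat)
  if (!is.null(fit$i_hat)) {
    sol$i_hat <- fit$i_hat
    sol$total_effect <- fit$i_hat + fit$b_hat
  }
  utils::write.csv(sol, emit("solutions.csv"), row.names = FALSE)
}
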