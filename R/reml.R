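#' Fit the animal model by REML
#'
#' Estimates variance components and predicts breeding values for the
#' repeatability animal model, with (`model = "FM"`) or without
#' (`model = "RM"`) the inbreeding-load effect. The restricted likelihood is
#' maximized directly: the residual variance is profiled out analytically
#' and the remaining variance ratios are optimized by Nelder-Mead, with the
#' 2x2 genetic covariance matrix `G` parameterized through its Cholesky
#' factor so positive semi-definiteness holds by construction. Each
#' likelihood evaluation is a sparse Cholesky factorization of the
#' mixed-model equations reusing a fixed symbolic pattern.
#'
#' Approximate standard errors are obtained from the numerically
#' differentiated observed information (Hessian of `-2 log L`) at the
#' optimum, on the variance-component scale.
#'
#' @inheritParams assemble_mme
#' @param start optional list of starting values (`sigma_u2`, `sigma_i2`,
#'   `sigma_ui`, `sigma_p2`, `sigma_e2`). Defaults: `sigma_e2` = half the
#'   phenotypic variance, `sigma_u2` = `sigma_p2` = a quarter each, and
#'   `sigma_i2` = the phenotypic variance (the load is expressed per fully
#'   inbred descendant, a much larger scale).
#' @param opts list of options: `maxit` (default 400), `reltol` (1e-10),
#'   `restarts` (1), `se` (TRUE: compute standard errors), `fix_r` (FALSE:
#'   when TRUE the genetic correlation between `u` and `i` is fixed at 0
#'   instead of estimated), `verbose` (0: every `verbose`-th likelihood
#'   evaluation is logged to the message stream with its `-2 logL` and
#'   parameter values).
#' @return an object of class `"inbload_fit"`: variance components and SEs,
#'   the inbreeding-depression coefficient `b_hat` (liters per unit, i.e.
#'   per fully inbred descendant) with its SE, fixed-effect solutions,
#'   BLUPs `u_hat` (and `i_hat` for FM, including animals with empty `K`
#'   columns, predicted through relatives), permanent-environment effects,
#'   `minus2logL`, convergence flag and iteration count.
#' @export
reml_fit <- function(ped, F = NULL, design = NULL, data,
                     model = c("FM", "RM"), start = NULL, opts = list(),
                     fixed = NULL) {
  model <- match.arg(model)
  if (is.null(F)) F <- compute_inbreeding(ped)
  o <- utils::modifyList(list(maxit = 400, reltol = 1e-10, restarts = 1,
                              se = TRUE, fix_r = FALSE, verbose = 0), opts)
  parts <- .build_design(ped, F, design, data, fixed, model)
  Ainv <- build_A_inverse(ped, F)
  prep <- .reml_prep(parts, Ainv)
  vy <- stats::var(parts$y)
  st <- list(sigma_e2 = 0.5 * vy, sigma_u2 = 0.25 * vy, sigma_p2 = 0.25 * vy,
             sigma_i2 = vy, sigma_ui = 0)
  if (!is.null(start)) st <- utils::modifyList(st, start)

  fm <- prep$parts$model == "FM"
  # parameter vector: log variance ratios and atanh-transformed genetic
  # correlation, bounded away from +/-1 (at a singular G the restricted
  # likelihood is not computable from the mixed-model equations)
  rmax <- sqrt(1 - 1e-6)
  fix_r <- fm && isTRUE(o$fix_r)
  th0 <- if (fm && !fix_r) {
    r0 <- st$sigma_ui / sqrt(st$sigma_u2 * st$sigma_i2)
    r0 <- min(max(r0, -0.99 * rmax), 0.99 * rmax)
    c(log(st$sigma_u2 / st$sigma_e2), log(st$sigma_i2 / st$sigma_e2),
      atanh(r0 / rmax), log(st$sigma_p2 / st$sigma_e2))
  } else if (fm) {
    c(log(st$sigma_u2 / st$sigma_e2), log(st$sigma_i2 / st$sigma_e2),
      log(st$sigma_p2 / st$sigma_e2))
  } else {
    c(log(st$sigma_u2 / st$sigma_e2), log(st$sigma_p2 / st$sigma_e2))
  }
  th2G <- function(th) {
    if (fm) {
      gu <- exp(th[1]); gi <- exp(th[2])
      r <- if (fix_r) 0 else rmax * tanh(th[3])
      list(G0 = matrix(c(gu, r * sqrt(gu * gi), r * sqrt(gu * gi), gi), 2, 2),
           gamma_p = exp(th[length(th)]))
    } else {
      list(G0 = matrix(exp(th[1]), 1, 1), gamma_p = exp(th[2]))
    }
  }
  n_obj <- 0L
  obj <- function(th) {
    g <- th2G(th)
    v <- .m2ll_at(prep, g$G0, g$gamma_p, se2 = NULL)$m2ll
    n_obj <<- n_obj + 1L
    if (o$verbose > 0 && n_obj %% o$verbose == 0L) {
      message(sprintf("eval %d: -2logL = %.6f  theta = [%s]", n_obj, v,
                      paste(sprintf("%.4f", th), collapse = ", ")))
    }
    v
  }
  neval <- 0L
  fit <- list(par = th0, value = obj(th0), convergence = 1L,
              counts = c(0, NA))
  for (r in seq_len(1 + o$restarts)) {
    res <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = o$maxit, reltol = o$reltol))
    neval <- neval + res$counts[1L]
    improved <- res$value <= fit$value + 1e-9
    if (improved) fit <- res
    if (r > 1L && improved &&
        abs(res$value - fit$value) < o$reltol * (1 + abs(fit$value))) break
  }
  g <- th2G(fit$par)
  final <- .m2ll_at(prep, g$G0, g$gamma_p, se2 = NULL)
  se2 <- final$se2
  comp <- list(sigma_u2 = g$G0[1, 1] * se2,
               sigma_i2 = if (fm) g$G0[2, 2] * se2 else NA_real_,
               sigma_ui = if (fm) g$G0[1, 2] * se2 else NA_real_,
               sigma_p2 = g$gamma_p * se2,
               sigma_e2 = se2)

  # unpack solutions
  sol <- final$sol
  n_fx <- parts$n_fx; n <- parts$n
  beta <- sol[seq_len(n_fx)]
  names(beta) <- parts$fixed_names
  u_hat <- sol[n_fx + seq_len(n)]
  names(u_hat) <- ped$id
  ofs <- n_fx + n
  i_hat <- NULL
  if (fm) {
    i_hat <- sol[ofs + seq_len(n)]
    names(i_hat) <- ped$id
    ofs <- ofs + n
  }
  p_hat <- sol[ofs + seq_len(parts$n_pe)]
  names(p_hat) <- parts$pe_ids
  b_hat <- if (parts$has_b) unname(beta["f"]) else NA_real_
  b_se <- NA_real_
  if (parts$has_b) {
    eb <- numeric(length(sol)); eb[which(parts$fixed_names == "f")] <- 1
    cinv_bb <- sum(eb * as.numeric(Matrix::solve(final$chol, eb, system = "A")))
    b_se <- sqrt(cinv_bb * se2)
  }

  se <- NULL
  if (isTRUE(o$se)) {
    se <- .reml_se(prep, c(fit$par, log(se2)), rmax, fm, fix_r)
  }
  res <- list(
    model = model, degenerate = parts$degenerate,
    components = comp, se = se,
    b_hat = b_hat, b_se = b_se, beta = beta,
    u_hat = u_hat, i_hat = i_hat, p_hat = p_hat,
    minus2logL = fit$value,
    converged = fit$convergence == 0L,
    iterations = neval,
    n_records = parts$nrec, n_animals = n, n_fixed = n_fx,
    threshold = if (!is.null(design)) design$threshold else NA_real_
  )
  class(res) <- "inbload_fit"
  res
}

# Numeric observed-information SEs. The Hessian of -2 logL is taken on the
# unconstrained transformed scale (log variance ratios, atanh correlation,
# log residual variance), where every finite point is a valid model, and
# mapped to the variance-component scale by the delta method. Directions
# the data do not inform have (near-)zero curvature and yield very large,
# finite SEs rather than failures.
.reml_se <- function(prep, t0, rmax, fm, fix_r = FALSE) {
  pars <- if (fm) {
    if (fix_r) c("sigma_u2", "sigma_i2", "sigma_p2", "sigma_e2")
    else c("sigma_u2", "sigma_i2", "sigma_ui", "sigma_p2", "sigma_e2")
  } else c("sigma_u2", "sigma_p2", "sigma_e2")
  nat <- function(t) {
    se2 <- exp(t[length(t)])
    if (fm && !fix_r) {
      gu <- exp(t[1]); gi <- exp(t[2]); r <- rmax * tanh(t[3])
      c(gu * se2, gi * se2, r * sqrt(gu * gi) * se2, exp(t[4]) * se2, se2)
    } else if (fm) {
      c(exp(t[1]) * se2, exp(t[2]) * se2, exp(t[3]) * se2, se2)
    } else {
      c(exp(t[1]) * se2, exp(t[2]) * se2, se2)
    }
  }
  f <- function(t) {
    se2 <- exp(t[length(t)])
    if (fm) {
      gu <- exp(t[1]); gi <- exp(t[2])
      r <- if (fix_r) 0 else rmax * tanh(t[3])
      G0 <- matrix(c(gu, r * sqrt(gu * gi), r * sqrt(gu * gi), gi), 2, 2)
      .m2ll_at(prep, G0, exp(t[length(t) - 1L]), se2 = se2)
    } else {
      .m2ll_at(prep, matrix(exp(t[1]), 1, 1), exp(t[2]), se2 = se2)
    }
  }
  k <- length(t0)
  h <- rep(1e-4, k)
  H <- matrix(NA_real_, k, k)
  fx <- f(t0)
  se <- rep(NA_real_, length(pars))
  if (is.finite(fx)) {
    for (a in seq_len(k)) {
      for (b in a:k) {
        ea <- eb <- numeric(k); ea[a] <- h[a]; eb[b] <- h[b]
        if (a == b) {
          H[a, a] <- (f(t0 + ea) - 2 * fx + f(t0 - ea)) / h[a]^2
        } else {
          H[a, b] <- H[b, a] <-
            (f(t0 + ea + eb) - f(t0 + ea - eb) -
             f(t0 - ea + eb) + f(t0 - ea - eb)) / (4 * h[a] * h[b])
        }
      }
    }
    if (all(is.finite(H))) {
      # numeric Jacobian of the natural parameters
      J <- matrix(0, length(pars), k)
      for (a in seq_len(k)) {
        ea <- numeric(k); ea[a] <- h[a]
        J[, a] <- (nat(t0 + ea) - nat(t0 - ea)) / (2 * h[a])
      }
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
      # flat or numerically negative curvature directions carry essentially
      # no information: invert against a tiny floor, giving large finite SEs
      floor_ev <- max(abs(ev$values)) * 1e-12 + 1e-300
      inv_vals <- 1 / pmax(ev$values, floor_ev)
      Vt <- ev$vectors %*% (2 * inv_vals * t(ev$vectors))
      Vn <- J %*% Vt %*% t(J)
      dv <- diag(Vn)
      se <- ifelse(is.finite(dv) & dv >= 0, sqrt(dv), NA_real_)
    }
  }
  names(se) <- pars
  as.list(se)
}

#' @export
print.inbload_fit <- function(x, ...) {
  cat(sprintf("%s animal model fit by REML (%d records, %d animals)\n",
              x$model, x$n_records, x$n_animals))
  cmp <- x$components
  fmt <- function(v, s) {
    if (is.null(s) || is.na(s)) sprintf("%.4g", v)
    else sprintf("%.4g (%.3g)", v, s)
  }
  for (nm in names(cmp)) {
    if (!is.na(cmp[[nm]])) {
      cat(sprintf("  %-9s %s\n", nm, fmt(cmp[[nm]], x$se[[nm]])))
    }
  }
  cat(sprintf("  b         %s\n", fmt(x$b_hat, x$b_se)))
  cat(sprintf("  -2logL    %.6f  (converged: %s, %d evaluations)\n",
              x$minus2logL, x$converged, x$iterations))
  invisible(x)
}

#' Likelihood-ratio test of the inbreeding-load variance
#'
#' Compares the full model (with inbreeding load) to the reduced model by
#' `LRT = (-2 logL_RM) - (-2 logL_FM)`. Because the null value of the load
#' variance lies on the boundary of the parameter space, the statistic is
#' referred to the mixture `1/2 chi2_0 + 1/2 chi2_1`:
#' `p = 1/2 Pr(chi2_1 >= LRT)` for a positive statistic and `p = 1` at zero.
#'
#' @param fit_fm,fit_rm `"inbload_fit"` objects fitted on identical data and
#'   fixed-effect structure, or bare numeric `-2 logL` values.
#' @return a list of class `"inbload_lrt"` with `statistic` and `p_value`.
#' @examples
#' likelihood_ratio_test(5379562.702, 5379715.675)$statistic  # 152.973
#' @export
likelihood_ratio_test <- function(fit_fm, fit_rm) {
  m2_fm <- if (inherits(fit_fm, "inbload_fit")) fit_fm$minus2logL else fit_fm
  m2_rm <- if (inherits(fit_rm, "inbload_fit")) fit_rm$minus2logL else fit_rm
  if (inherits(fit_fm, "inbload_fit") && inherits(fit_rm, "inbload_fit")) {
    if (fit_fm$n_records != fit_rm$n_records ||
        fit_fm$n_fixed != fit_rm$n_fixed) {
      stop("models were not fitted on identical data / fixed-effect structure")
    }
  }
  stat <- m2_rm - m2_fm
  if (stat < -1e-6) {
    stop("negative likelihood-ratio statistic (", format(stat),
         "): model nesting violated")
  }
  if (stat < 0) {
    warning("tiny negative LRT statistic clipped to 0")
    stat <- 0
  }
  p <- if (stat > 0) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  res <- list(statistic = stat, p_value = p)
  class(res) <- "inbload_lrt"
  res
}

#' @export
print.inbload_lrt <- function(x, ...) {
  cat(sprintf("LRT (1/2 chi2_0 + 1/2 chi2_1 null): statistic = %.3f, p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Derived summaries from variance components
#'
#' Computes the derived quantities usually reported alongside the model fit,
#' from bare component values: the load variance rescaled to a reference
#' inbreeding level (`sigma_i2 * F_ref^2`), the genetic correlation
#' `r_ui = sigma_ui / sqrt(sigma_u2 sigma_i2)`, the inbreeding-depression
#' rate as a percentage of the trait mean per `delta_F` of inbreeding
#' (`|b| delta_F / mean * 100`), and the expected depression in trait units
#' at `F_ref` (`b * F_ref`).
#'
#' @param sigma_u2,sigma_i2,sigma_ui genetic (co)variance components
#'   (trait units squared; the load is scaled per fully inbred descendant).
#' @param b inbreeding-depression coefficient (trait units per unit
#'   inbreeding).
#' @param trait_mean population mean of the trait.
#' @param F_ref reference inbreeding level for rescaling (default 0.10).
#' @param delta_F inbreeding increment for the depression rate (default
#'   0.01, i.e. 1%).
#' @return a list with `rescaled_load_variance`, `r_ui` (`NA` when
#'   `sigma_i2 = 0`), `r_defined`, `depression_rate_pct`,
#'   `depression_at_F_ref`.
#' @examples
#' summarize_components(847.9, 11804, -289, b = -109, trait_mean = 193)
#' @export
summarize_components <- function(sigma_u2, sigma_i2, sigma_ui, b, trait_mean,
                                 F_ref = 0.10, delta_F = 0.01) {
  r_defined <- is.finite(sigma_i2) && sigma_i2 > 0 && sigma_u2 > 0
  list(
    rescaled_load_variance = sigma_i2 * F_ref^2,
    r_ui = if (r_defined) sigma_ui / sqrt(sigma_u2 * sigma_i2) else NA_real_,
    r_defined = r_defined,
    depression_rate_pct = abs(b) * delta_F / trait_mean * 100,
    depression_at_F_ref = b * F_ref
  )
}

#' Summarize a fitted full model
#'
#' Reports the derived quantities of [summarize_components()] for a
#' converged FM fit plus the distribution of the predicted inbreeding loads:
#' the per-animal total inbreeding effect `i_hat + b_hat` expressed by a
#' fully inbred descendant, and the fractions of animals whose predicted
#' load is positive before and after adding the overall depression `b_hat`.
#'
#' @param fit an `"inbload_fit"` from [reml_fit()] with `model = "FM"`.
#' @param trait_mean population mean of the trait.
#' @param F_ref,delta_F see [summarize_components()].
#' @return a list of class `"inbload_fit_summary"`.
#' @export
summarize_fit <- function(fit, trait_mean, F_ref = 0.10, delta_F = 0.01) {
  stopifnot(inherits(fit, "inbload_fit"))
  if (fit$model != "FM" || is.null(fit$i_hat)) {
    stop("summarize_fit requires a full-model (FM) fit with load effects")
  }
  cmp <- fit$components
  base <- summarize_components(cmp$sigma_u2, cmp$sigma_i2, cmp$sigma_ui,
                               fit$b_hat, trait_mean, F_ref, delta_F)
  i_hat <- fit$i_hat
  total <- i_hat + fit$b_hat
  res <- c(base, list(
    total_effect = total,
    pct_positive_load = 100 * mean(i_hat > 0),
    pct_positive_total = 100 * mean(total > 0),
    i_hat_summary = c(mean = mean(i_hat), sd = stats::sd(i_hat),
                      stats::quantile(i_hat, c(0, 0.25, 0.5, 0.75, 1))),
    trait_mean = trait_mean, F_ref = F_ref, delta_F = delta_F
  ))
  class(res) <- "inbload_fit_summary"
  res
}

#' @export
print.inbload_fit_summary <- function(x, ...) {
  cat("full-model summary\n")
  cat(sprintf("  rescaled load variance (F = %.2f): %.4g\n",
              x$F_ref, x$rescaled_load_variance))
  cat(sprintf("  r(u, i): %s\n",
              if (x$r_defined) sprintf("%.3f", x$r_ui) else "undefined"))
  cat(sprintf("  depression: %.2f%% of the mean per %.0f%% inbreeding\n",
              x$depression_rate_pct, 100 * x$delta_F))
  cat(sprintf("  animals with positive load: %.1f%% (%.1f%% after adding b)\n",
              x$pct_positive_load, x$pct_positive_total))
  invisible(x)
}
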