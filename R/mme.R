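# Mixed-model equation assembly for the repeatability animal model
#   y = X beta + f b + Z_u u + Z_u K i + Z_p p + e
# with (u, i) ~ N(0, G x A) (Kronecker), p ~ N(0, I sigma_p^2),
# e ~ N(0, I sigma_e^2). The reduced model (RM) omits i.

# Build the record-level design pieces shared by assemble_mme() and
# reml_fit(). Fixed factors use dummy coding that drops the LAST level of
# each factor (plus a global intercept); the inbreeding covariate f is the
# last fixed column. Returns sparse matrices throughout.
.build_design <- function(ped, F, design, data, fixed = NULL,
                          model = c("FM", "RM")) {
  model <- match.arg(model)
  stopifnot(inherits(ped, "pedigree"), is.data.frame(data))
  if (!all(c("animal_id", "y") %in% names(data))) {
    stop("phenotype table must have columns 'animal_id' and 'y'")
  }
  n <- nrow(ped)
  arow <- match(data$animal_id, ped$id)
  if (anyNA(arow)) {
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(utils::head(unique(data$animal_id[is.na(arow)])), collapse = ", "))
  }
  nrec <- nrow(data)
  if (is.null(fixed)) {
    fixed <- setdiff(names(data), c("animal_id", "y", "f"))
  }

  # intercept + drop-last-level dummies per factor
  Xs <- list(Matrix::Matrix(1, nrec, 1, sparse = TRUE,
                            dimnames = list(NULL, "(Intercept)")))
  for (fc in fixed) {
    v <- factor(data[[fc]])
    lev <- levels(v)
    if (length(lev) < 2L) next
    keep <- lev[-length(lev)]
    Mi <- Matrix::sparseMatrix(i = which(v %in% keep),
                               j = match(v[v %in% keep], keep),
                               x = 1, dims = c(nrec, length(keep)),
                               dimnames = list(NULL, paste0(fc, ":", keep)))
    Xs[[length(Xs) + 1L]] <- Mi
  }
  f <- if ("f" %in% names(data)) data$f else unname(F[arow])
  has_b <- stats::sd(f) > 0
  if (!has_b) {
    warning("inbreeding covariate is constant; depression coefficient b dropped")
  } else {
    Xs[[length(Xs) + 1L]] <- Matrix::Matrix(f, nrec, 1, sparse = TRUE,
                                            dimnames = list(NULL, "f"))
  }
  X <- do.call(cbind, Xs)

  Zu <- Matrix::sparseMatrix(i = seq_len(nrec), j = arow, x = 1,
                             dims = c(nrec, n))
  pe_rows <- sort(unique(arow))
  Zp <- Matrix::sparseMatrix(i = seq_len(nrec), j = match(arow, pe_rows),
                             x = 1, dims = c(nrec, length(pe_rows)))

  degenerate <- FALSE
  if (model == "FM") {
    if (is.null(design) || length(design$K@x) == 0L) {
      warning("FM requested but K has no entries; model degenerates to RM")
      model <- "RM"
      degenerate <- TRUE
    } else if (design$n != n) {
      stop("dimension mismatch: load design is for ", design$n,
           " animals but pedigree has ", n)
    }
  }
  W <- if (model == "FM") cbind(X, Zu, Zu %*% design$K, Zp) else cbind(X, Zu, Zp)

  list(model = model, degenerate = degenerate, W = W, y = data$y,
       X = X, n_fx = ncol(X), n = n, n_pe = length(pe_rows),
       pe_ids = ped$id[pe_rows], nrec = nrec, has_b = has_b,
       fixed_names = colnames(X), arow = arow, f = f)
}

# Precision penalty for the random effects on the ratio scale
# (gamma = sigma^2 / sigma_e^2). G0 is the 2x2 ratio-scale G for FM, or the
# scalar gamma_u for RM. The fixed block is structurally present (zeros).
.penalty <- function(parts, Ainv, G0, gamma_p) {
  zero_fx <- Matrix::Matrix(0, parts$n_fx, parts$n_fx, sparse = TRUE)
  if (parts$model == "FM") {
    # closed-form 2x2 inverse: never errors, caller guards det > 0
    dt <- G0[1, 1] * G0[2, 2] - G0[1, 2] * G0[2, 1]
    Gi <- matrix(c(G0[2, 2], -G0[2, 1], -G0[1, 2], G0[1, 1]), 2, 2) / dt
    kron <- rbind(cbind(Gi[1, 1] * Ainv, Gi[1, 2] * Ainv),
                  cbind(Gi[2, 1] * Ainv, Gi[2, 2] * Ainv))
    Matrix::bdiag(zero_fx, kron, Matrix::Diagonal(parts$n_pe, 1 / gamma_p))
  } else {
    Matrix::bdiag(zero_fx, (1 / G0[1, 1]) * Ainv,
                  Matrix::Diagonal(parts$n_pe, 1 / gamma_p))
  }
}

# log|Sigma0| on the ratio scale (Sigma0 = covariance of all random effects
# divided by sigma_e^2)
.logdet_sigma0 <- function(parts, logdet_A, G0, gamma_p) {
  if (parts$model == "FM") {
    parts$n * as.numeric(determinant(G0, logarithm = TRUE)$modulus) +
      2 * logdet_A + parts$n_pe * log(gamma_p)
  } else {
    parts$n * log(G0[1, 1]) + logdet_A + parts$n_pe * log(gamma_p)
  }
}

#' Assemble the mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side of the mixed-model
#' equations for the full (FM) or reduced (RM) repeatability animal model at
#' given variance components. Fixed effects are dummy-coded dropping the
#' last level of each factor; the inbreeding covariate enters as the last
#' fixed column. The joint precision of `(u, i)` is `G^-1 (x) A^-1`; the
#' permanent-environment block is `I / sigma_p^2`.
#'
#' @param ped a [pedigree].
#' @param F inbreeding coefficients; computed if omitted.
#' @param design a `"load_design"` (required for FM; may be `NULL` for RM).
#' @param data phenotype `data.frame` with columns `animal_id`, `y`, optional
#'   `f` (defaults to pedigree inbreeding), and fixed-effect columns.
#' @param vc list of variance components: `sigma_u2`, `sigma_p2`, `sigma_e2`
#'   and (FM) `sigma_i2`, `sigma_ui`.
#' @param model `"FM"` or `"RM"`.
#' @param fixed character vector naming the fixed-effect factor columns in
#'   `data`; default: every column other than `animal_id`, `y`, `f`.
#' @return a list with the coefficient matrix `C`, right-hand side `rhs`,
#'   and `index`, a named list mapping effect blocks to equation ranges.
#' @export
assemble_mme <- function(ped, F = NULL, design = NULL, data, vc,
                         model = c("FM", "RM"), fixed = NULL) {
  model <- match.arg(model)
  if (is.null(F)) F <- compute_inbreeding(ped)
  parts <- .build_design(ped, F, design, data, fixed, model)
  Ainv <- build_A_inverse(ped, F)
  se2 <- vc$sigma_e2
  stopifnot(se2 > 0, vc$sigma_u2 > 0, vc$sigma_p2 > 0)
  if (parts$model == "FM") {
    G0 <- matrix(c(vc$sigma_u2, vc$sigma_ui, vc$sigma_ui, vc$sigma_i2),
                 2, 2) / se2
    if (vc$sigma_i2 <= 0) stop("sigma_i2 must be > 0 for FM")
  } else {
    G0 <- matrix(vc$sigma_u2 / se2, 1, 1)
  }
  Pen <- .penalty(parts, Ainv, G0, vc$sigma_p2 / se2)
  C <- (Matrix::crossprod(parts$W) + Pen) / se2
  rhs <- Matrix::crossprod(parts$W, parts$y) / se2
  idx <- list(fixed = seq_len(parts$n_fx),
              u = parts$n_fx + seq_len(parts$n))
  ofs <- parts$n_fx + parts$n
  if (parts$model == "FM") {
    idx$i <- ofs + seq_len(parts$n)
    ofs <- ofs + parts$n
  }
  idx$pe <- ofs + seq_len(parts$n_pe)
  list(C = Matrix::forceSymmetric(C), rhs = rhs, index = idx,
       model = parts$model, fixed_names = parts$fixed_names,
       pe_ids = parts$pe_ids)
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates `-2 log L_REML` for the FM or RM model at the supplied variance
#' components, on the same constant convention for both models so that their
#' difference is the likelihood-ratio statistic. Useful for profiling,
#' grid-search checks, and model comparison at externally estimated
#' components.
#'
#' @inheritParams assemble_mme
#' @return the scalar `-2 log L_REML`.
#' @export
reml_loglik <- function(ped, F = NULL, design = NULL, data, vc,
                        model = c("FM", "RM"), fixed = NULL) {
  model <- match.arg(model)
  if (is.null(F)) F <- compute_inbreeding(ped)
  parts <- .build_design(ped, F, design, data, fixed, model)
  Ainv <- build_A_inverse(ped, F)
  prep <- .reml_prep(parts, Ainv)
  se2 <- vc$sigma_e2
  if (parts$model == "FM") {
    G0 <- matrix(c(vc$sigma_u2, vc$sigma_ui, vc$sigma_ui, vc$sigma_i2),
                 2, 2) / se2
  } else {
    G0 <- matrix(vc$sigma_u2 / se2, 1, 1)
  }
  .m2ll_at(prep, G0, vc$sigma_p2 / se2, se2)
}

# One-time REML preparation: cross-products, symbolic Cholesky pattern.
.reml_prep <- function(parts, Ainv) {
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(parts$W))
  Wty <- as.numeric(Matrix::crossprod(parts$W, parts$y))
  prep <- list(parts = parts, Ainv = Ainv,
               logdet_A = attr(Ainv, "logdet_A"),
               WtW = WtW, Wty = Wty, yty = sum(parts$y^2),
               np = parts$nrec - parts$n_fx)
  # symbolic factorization reused across evaluations (pattern is constant:
  # scalar * sparse keeps explicit zeros)
  G0_init <- if (parts$model == "FM") diag(2) else matrix(1, 1, 1)
  C0 <- Matrix::forceSymmetric(WtW + .penalty(parts, Ainv, G0_init, 1))
  prep$chol <- Matrix::Cholesky(C0, LDL = FALSE, perm = TRUE, super = TRUE)
  prep
}

# -2 logL at ratio-scale (G0, gamma_p) and residual variance se2.
# Profiled form: pass se2 = NULL to minimize analytically over sigma_e^2;
# returns list(m2ll, se2, sol) in that case.
.m2ll_at <- function(prep, G0, gamma_p, se2 = NULL) {
  parts <- prep$parts
  fail <- if (is.null(se2)) list(m2ll = Inf) else Inf
  if (!is.finite(gamma_p) || gamma_p <= 0) return(fail)
  if (!all(is.finite(G0))) return(fail)
  if (parts$model == "FM") {
    # keep the genetic correlation away from +/-1: at a (nearly) singular G
    # the precision penalty swamps the data cross-products and the computed
    # likelihood is meaningless, creating phantom boundary optima
    dt <- G0[1, 1] * G0[2, 2] - G0[1, 2] * G0[2, 1]
    if (G0[1, 1] <= 0 || G0[2, 2] <= 0 || dt <= 1e-7 * G0[1, 1] * G0[2, 2]) {
      return(fail)
    }
  } else if (G0[1, 1] <= 0) return(fail)
  C0 <- Matrix::forceSymmetric(prep$WtW + .penalty(parts, prep$Ainv, G0, gamma_p))
  ch <- tryCatch(Matrix::update(prep$chol, C0), error = function(e) NULL)
  if (is.null(ch)) return(fail)
  sol <- as.numeric(Matrix::solve(ch, prep$Wty, system = "A"))
  yPy <- prep$yty - sum(sol * prep$Wty)
  if (!is.finite(yPy) || yPy <= 0) return(fail)
  ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  ldS <- .logdet_sigma0(parts, prep$logdet_A, G0, gamma_p)
  np <- prep$np
  if (is.null(se2)) {
    se2_hat <- yPy / np
    m2ll <- np * (log(2 * pi) + 1 + log(se2_hat)) + ldC + ldS
    list(m2ll = m2ll, se2 = se2_hat, sol = sol, chol = ch)
  } else {
    np * log(2 * pi) + np * log(se2) + ldC + ldS + yPy / se2
  }
}
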