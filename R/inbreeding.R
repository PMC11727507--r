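#' Pedigree inbreeding coefficients
#'
#' Computes the inbreeding coefficient `F` of every animal, defined as half
#' the additive relationship between its parents. Two algorithms are
#' provided and must agree: a memory-light recursion that accumulates the
#' diagonal of the relationship matrix through the gene-flow decomposition
#' `A = T D T'` (suitable for large pedigrees), and the dense tabular method
#' (quadratic in pedigree size, used as a cross-check).
#'
#' @param ped a [pedigree].
#' @param method `"recursive"` (default) or `"tabular"`.
#' @return named numeric vector of inbreeding coefficients, names = animal ids.
#' @examples
#' ped <- pedigree(1:4, c(0, 0, 1, 1), c(0, 0, 2, 3))
#' compute_inbreeding(ped)  # dam-son mating: F = 0.25 for animal 4
#' @export
compute_inbreeding <- function(ped, method = c("recursive", "tabular")) {
  stopifnot(inherits(ped, "pedigree"))
  method <- match.arg(method)
  n <- nrow(ped)
  if (method == "tabular") {
    A <- additive_relationship(ped)
    Fv <- diag(A) - 1
    names(Fv) <- ped$id
    return(Fv)
  }
  sr <- ped$sire_row; dr <- ped$dam_row
  Fv <- numeric(n)
  m  <- numeric(n)  # Mendelian sampling variances, filled as F becomes known
  L  <- numeric(n)
  for (i in seq_len(n)) {
    s <- sr[i]; d <- dr[i]
    if (is.na(s) && is.na(d)) {
      m[i] <- 1
    } else if (!is.na(s) && !is.na(d)) {
      m[i] <- 0.5 - 0.25 * (Fv[s] + Fv[d])
    } else {
      l <- if (is.na(s)) d else s
      m[i] <- 0.75 - 0.25 * Fv[l]
    }
    if (is.na(s) || is.na(d)) {
      Fv[i] <- 0
      next
    }
    # a(i,i) = sum_k T[i,k]^2 m_k ; F_i = a(i,i) - 1
    L[i] <- 1
    acc <- 0
    for (k in i:1) {
      lk <- L[k]
      if (lk == 0) next
      acc <- acc + lk * lk * m[k]
      ks <- sr[k]; kd <- dr[k]
      if (!is.na(ks)) L[ks] <- L[ks] + 0.5 * lk
      if (!is.na(kd)) L[kd] <- L[kd] + 0.5 * lk
      L[k] <- 0
    }
    Fv[i] <- acc - 1
  }
  names(Fv) <- ped$id
  Fv
}

#' Mendelian sampling variances
#'
#' Returns the within-family (Mendelian sampling) variance `phi_jj` attached
#' to each animal in the tabular relationship recursion:
#' `1/4 (1 - F_s) + 1/4 (1 - F_d)` when both parents are known,
#' `1/2 + 1/4 (1 - F_l)` when only parent `l` is known, and `1` when both
#' parents are unknown.
#'
#' @param ped a [pedigree].
#' @param F inbreeding coefficients from [compute_inbreeding()]; computed if
#'   omitted.
#' @return named numeric vector `phi`, values in `[1/4, 1]` for parental
#'   `F < 1`.
#' @export
mendelian_variance <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(F)) F <- compute_inbreeding(ped)
  stopifnot(length(F) == nrow(ped))
  sr <- ped$sire_row; dr <- ped$dam_row
  Fs <- ifelse(is.na(sr), NA_real_, F[sr])
  Fd <- ifelse(is.na(dr), NA_real_, F[dr])
  phi <- ifelse(is.na(sr) & is.na(dr), 1,
         ifelse(!is.na(sr) & !is.na(dr),
                0.25 * (1 - Fs) + 0.25 * (1 - Fd),
                0.5 + 0.25 * (1 - ifelse(is.na(sr), Fd, Fs))))
  names(phi) <- ped$id
  phi
}

#' Dense additive relationship matrix (tabular method)
#'
#' Builds the full numerator relationship matrix `A` by the tabular method.
#' Quadratic in memory; intended for cross-checks and small systems.
#'
#' @param ped a [pedigree].
#' @return dense `n x n` matrix with dimnames = animal ids.
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  sr <- ped$sire_row; dr <- ped$dam_row
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- sr[j]; d <- dr[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      row <- numeric(j - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, prev]
      if (!is.na(d)) row <- row + 0.5 * A[d, prev]
      A[j, prev] <- row
      A[prev, j] <- row
    }
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[j, j] <- 1 + 0.5 * asd
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Equivalent complete generations
#'
#' Pedigree-completeness index per animal: the sum over known ancestors of
#' `(1/2)^g`, with `g` the generation distance, counting each ancestor once
#' per path. Computed by the recursion
#' `ecg_j = sum over known parents of (1/2) (1 + ecg_parent)`.
#'
#' @param ped a [pedigree].
#' @return named numeric vector; founders have value 0.
#' @export
equivalent_complete_generations <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  sr <- ped$sire_row; dr <- ped$dam_row
  ecg <- numeric(n)
  for (j in seq_len(n)) {
    e <- 0
    if (!is.na(sr[j])) e <- e + 0.5 * (1 + ecg[sr[j]])
    if (!is.na(dr[j])) e <- e + 0.5 * (1 + ecg[dr[j]])
    ecg[j] <- e
  }
  names(ecg) <- ped$id
  ecg
}
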