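#' Sparse inverse of the numerator relationship matrix
#'
#' Builds `A^-1` directly from the pedigree by Henderson's rules, accounting
#' for inbreeding. For each animal `j` with Mendelian sampling variance
#' `m_j` (`1/2 - 1/4 (F_s + F_d)` with both parents known, `3/4 - 1/4 F_l`
#' with one known parent `l`, `1` with none), the contributions are
#' `1/m_j` at `(j, j)`, `-1/(2 m_j)` at `(j, parent)`, and `1/(4 m_j)` at
#' each `(parent, parent')` pair over the known parents.
#'
#' @param ped a [pedigree].
#' @param F inbreeding coefficients; computed if omitted.
#' @return a symmetric sparse matrix with dimnames = animal ids, plus
#'   attribute `"logdet_A"` holding `log|A| = sum(log m_j)`.
#' @export
build_A_inverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (is.null(F)) F <- compute_inbreeding(ped)
  if (any(F < 0 | F >= 1)) stop("inbreeding coefficients must lie in [0, 1)")
  sr <- ped$sire_row; dr <- ped$dam_row
  m <- unname(mendelian_variance(ped, F))  # identical to Henderson's m_j
  w <- 1 / m
  j_all <- seq_len(n)

  ii <- j_all; jj <- j_all; xx <- w  # diagonal

  for (pr in list(sr, dr)) {
    known <- which(!is.na(pr))
    p <- pr[known]
    ii <- c(ii, known, p)
    jj <- c(jj, p, known)
    xx <- c(xx, rep.int(-0.5, 2 * length(known)) * w[c(known, known)])
  }
  both <- which(!is.na(sr) & !is.na(dr))
  one  <- which(xor(is.na(sr), is.na(dr)))
  if (length(both)) {
    s <- sr[both]; d <- dr[both]; wb <- w[both] / 4
    ii <- c(ii, s, d, s, d)
    jj <- c(jj, s, d, d, s)
    xx <- c(xx, wb, wb, wb, wb)
  }
  if (length(one)) {
    l <- ifelse(is.na(sr[one]), dr[one], sr[one])
    ii <- c(ii, l); jj <- c(jj, l); xx <- c(xx, w[one] / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "logdet_A") <- sum(log(m))
  Ainv
}
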