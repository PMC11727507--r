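#' Parent-pointer matrix P
#'
#' Sparse `n x n` matrix with a single entry 0.5 at (child, sire) and
#' (child, dam) for each known parent slot; founders have empty rows and the
#' diagonal is zero.
#'
#' @param ped a [pedigree].
#' @return a `dgCMatrix` with dimnames = animal ids.
#' @export
build_parent_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  i <- c(which(!is.na(ped$sire_row)), which(!is.na(ped$dam_row)))
  j <- c(ped$sire_row[!is.na(ped$sire_row)], ped$dam_row[!is.na(ped$dam_row)])
  P <- Matrix::sparseMatrix(i = i, j = j, x = 0.5, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  P
}

#' Load design matrices K = T(I - P)
#'
#' Builds the sparse matrices linking an animal's record to the
#' inbreeding-load effects of its ancestors: `T` holds the partial inbreeding
#' coefficients (`T[j,k] = F_j(k)`), `P` the 0.5 parent pointers, and
#' `K = T(I - P)` expresses each animal's inbreeding in terms of the
#' Mendelian-sampling deviations of its ancestors' load effects. Entries of
#' `K` with `|K[j,k]| <= threshold` are dropped after the exact product;
#' `T` is retained unthresholded for diagnostics. All three matrices are
#' strictly lower triangular under the pedigree ordering, which is asserted.
#'
#' @param partials a `"partial_inbreeding"` object (see
#'   [compute_partial_inbreeding()]).
#' @param P sparse parent matrix from [build_parent_matrix()], built on the
#'   same pedigree.
#' @param threshold magnitude below which final `K` entries are dropped;
#'   default 0.01, set 0 to keep the exact product.
#' @return a list of class `"load_design"` with elements `T`, `P`, `K`,
#'   `threshold`, `n`.
#' @export
build_K <- function(partials, P, threshold = 0.01) {
  stopifnot(inherits(partials, "partial_inbreeding"))
  stopifnot(threshold >= 0)
  n <- attr(partials, "n_animals")
  if (is.null(n)) n <- nrow(P)
  if (nrow(P) != n || ncol(P) != n) {
    stop("dimension mismatch: partials are for ", n, " animals but P is ",
         nrow(P), " x ", ncol(P))
  }
  ids <- rownames(P)
  Tm <- Matrix::sparseMatrix(
    i = match(partials$descendant, ids),
    j = match(partials$ancestor, ids),
    x = partials$partial_f, dims = c(n, n), dimnames = list(ids, ids)
  )
  K <- Tm %*% (Matrix::Diagonal(n) - P)
  K <- methods::as(Matrix::drop0(K), "CsparseMatrix")
  stopifnot(Matrix::isTriangular(Tm, upper = FALSE),
            Matrix::isTriangular(K, upper = FALSE),
            all(Matrix::diag(K) == 0))
  if (threshold > 0) {
    K@x[abs(K@x) <= threshold] <- 0
    K <- Matrix::drop0(K)
  }
  dimnames(K) <- list(ids, ids)
  res <- list(T = Tm, P = P, K = K, threshold = threshold, n = n)
  class(res) <- "load_design"
  res
}

#' @export
print.load_design <- function(x, ...) {
  cat(sprintf(
    "load design: %d animals, %d partial coefficients, %d K entries (threshold %g)\n",
    x$n, length(x$T@x), length(x$K@x), x$threshold))
  invisible(x)
}

#' Write the K matrix in sparse coordinate format
#'
#' One line per stored entry: `row_animal column_animal value`, matching the
#' triplet dialect of [write_partials()].
#'
#' @param design a `"load_design"` object.
#' @param path output path.
#' @param delimiter field separator.
#' @export
write_K <- function(design, path, delimiter = " ") {
  stopifnot(inherits(design, "load_design"))
  K <- methods::as(design$K, "TsparseMatrix")
  ids <- rownames(design$K)
  df <- data.frame(row = ids[K@i + 1L], column = ids[K@j + 1L],
                   value = formatC(K@x, format = "g", digits = 17))
  df <- df[order(as.integer(df$row), as.integer(df$column)), ]
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
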