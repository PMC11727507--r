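#' Mendelian decomposition of inbreeding into partial coefficients
#'
#' Decomposes each animal's inbreeding coefficient into partial inbreeding
#' coefficients `F_j(k)` attributed to specific ancestors `k`, so that
#' `sum_k F_j(k) = F_j`. Every animal, founder or not, acts as a partial
#' founder through its Mendelian sampling variance `phi_kk`.
#'
#' The method runs the tabular relationship recursion with the `phi` matrix
#' zeroed everywhere except `phi_kk`, once per candidate ancestor `k`.
#' Because that recursion is linear in `phi`, the single-ancestor
#' relationship matrix is the rank-one outer product
#' `A^(k) = phi_kk t t'`, with `t` the vector of expected gene-flow
#' contributions of `k` (`t_k = 1`, `t_j = (t_sire + t_dam)/2`). The sweep
#' therefore reduces to one downward gene-flow pass per ancestor and
#' `F_j(k) = 1/2 phi_kk t_(sire of j) t_(dam of j)`.
#'
#' Candidate ancestors are screened first: only animals present in both the
#' sire-side and the dam-side ancestor set of at least one inbred animal can
#' generate inbreeding, which in practice is a small fraction of the
#' pedigree. The screening provably drops only zero triplets.
#'
#' @param ped a [pedigree].
#' @param phi Mendelian sampling variances from [mendelian_variance()];
#'   computed if omitted.
#' @param F inbreeding coefficients; computed if omitted.
#' @return a `data.frame` of class `"partial_inbreeding"` with columns
#'   `descendant`, `ancestor`, `partial_f` (strictly positive), carrying the
#'   total inbreeding vector as attribute `"F"` and the founder ids as
#'   attribute `"founders"`.
#' @examples
#' ped <- pedigree(1:4, c(0, 0, 1, 1), c(0, 0, 2, 3))
#' compute_partial_inbreeding(ped)  # single triplet F_4(1) = 0.25
#' @export
compute_partial_inbreeding <- function(ped, phi = NULL, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (is.null(F)) F <- compute_inbreeding(ped)
  if (is.null(phi)) phi <- mendelian_variance(ped, F)
  stopifnot(length(phi) == n, length(F) == n)
  sr <- ped$sire_row; dr <- ped$dam_row

  inbred <- which(F > 0)
  out_d <- integer(0); out_a <- integer(0); out_f <- numeric(0)
  if (length(inbred)) {
    cand <- .candidate_ancestors(sr, dr, inbred)
    for (k in cand) {
      # downward gene-flow pass restricted to descendants of k
      t <- numeric(n)
      t[k] <- 1
      if (k < n) {
        for (j in (k + 1L):n) {
          s <- sr[j]; d <- dr[j]
          v <- 0
          if (!is.na(s)) v <- v + 0.5 * t[s]
          if (!is.na(d)) v <- v + 0.5 * t[d]
          t[j] <- v
        }
      }
      js <- inbred[!is.na(sr[inbred]) & !is.na(dr[inbred])]
      js <- js[js > k]
      ts <- t[sr[js]]; td <- t[dr[js]]
      pos <- ts > 0 & td > 0
      if (any(pos)) {
        js <- js[pos]
        out_d <- c(out_d, js)
        out_a <- c(out_a, rep.int(k, length(js)))
        out_f <- c(out_f, 0.5 * phi[k] * ts[pos] * td[pos])
      }
    }
  }
  ord <- order(out_d, out_a)
  res <- data.frame(descendant = ped$id[out_d][ord],
                    ancestor = ped$id[out_a][ord],
                    partial_f = unname(out_f[ord]))
  attr(res, "F") <- F
  attr(res, "founders") <- ped$id[is.na(sr) & is.na(dr)]
  attr(res, "n_animals") <- n
  class(res) <- c("partial_inbreeding", "data.frame")
  res
}

# Ancestor sets (including self) for the parents of inbred animals; a
# candidate is any animal lying on both the sire side and the dam side of at
# least one inbred animal.
.candidate_ancestors <- function(sr, dr, inbred) {
  n <- length(sr)
  cache <- vector("list", n)
  anc <- function(i) {
    if (!is.null(cache[[i]])) return(cache[[i]])
    s <- sr[i]; d <- dr[i]
    res <- i
    if (!is.na(s)) res <- c(res, anc(s))
    if (!is.na(d)) res <- c(res, anc(d))
    res <- unique(res)
    cache[[i]] <<- res
    res
  }
  cand <- integer(0)
  for (j in inbred) {
    s <- sr[j]; d <- dr[j]
    if (is.na(s) || is.na(d)) next
    cand <- unique(c(cand, intersect(anc(s), anc(d))))
  }
  sort(cand)
}

#' Summarize inbreeding and its decomposition
#'
#' Descriptive statistics for a pedigree's inbreeding structure: percentage
#' of inbred animals, the fractions of inbred animals with `F < 0.05` and
#' `F > 0.1`, mean `F` among inbred animals and overall, the number of
#' partial coefficients with their mean, SD and maximum, the number of
#' distinct ancestors generating inbreeding and how many of those are
#' founders, and per-ancestor descendant counts.
#'
#' @param F inbreeding vector from [compute_inbreeding()].
#' @param partials decomposition from [compute_partial_inbreeding()].
#' @return a list of class `"inbreeding_summary"` with components `table`
#'   (key-value `data.frame`) and `ancestor_counts` (per-ancestor number of
#'   inbred descendants).
#' @export
summarize_inbreeding <- function(F, partials) {
  stopifnot(inherits(partials, "partial_inbreeding"))
  n <- length(F)
  inbred <- F > 0
  n_inbred <- sum(inbred)
  counts <- if (nrow(partials)) table(partials$ancestor) else table(integer(0))
  founders <- attr(partials, "founders")
  anc_ids <- if (nrow(partials)) unique(partials$ancestor) else integer(0)
  tab <- data.frame(
    key = c("n_animals", "pct_inbred",
            "pct_inbred_F_lt_0.05", "pct_inbred_F_gt_0.1",
            "mean_F_inbred", "mean_F_overall",
            "n_partial_coefficients", "mean_partial_f", "sd_partial_f",
            "max_partial_f", "n_ancestors_involved", "n_founder_ancestors"),
    value = c(n, 100 * n_inbred / n,
              if (n_inbred) 100 * sum(F[inbred] < 0.05) / n_inbred else 0,
              if (n_inbred) 100 * sum(F[inbred] > 0.1) / n_inbred else 0,
              if (n_inbred) mean(F[inbred]) else 0,
              mean(F),
              nrow(partials),
              if (nrow(partials)) mean(partials$partial_f) else 0,
              if (nrow(partials) > 1L) stats::sd(partials$partial_f) else 0,
              if (nrow(partials)) max(partials$partial_f) else 0,
              length(anc_ids),
              sum(anc_ids %in% founders))
  )
  res <- list(table = tab,
              ancestor_counts = as.data.frame(counts,
                                              responseName = "n_descendants"))
  class(res) <- "inbreeding_summary"
  res
}

#' @export
print.inbreeding_summary <- function(x, ...) {
  cat("inbreeding summary\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write partial inbreeding coefficients to a delimited file
#'
#' One triplet per line with header `descendant ancestor partial_f`, full
#' double precision (17 significant digits).
#'
#' @param partials a `"partial_inbreeding"` object.
#' @param path output path.
#' @param delimiter field separator.
#' @export
write_partials <- function(partials, path, delimiter = " ") {
  stopifnot(inherits(partials, "partial_inbreeding"))
  df <- as.data.frame(partials)
  df$partial_f <- formatC(df$partial_f, format = "g", digits = 17)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
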