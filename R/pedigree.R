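#' Construct a pedigree
#'
#' Builds a validated, topologically sorted pedigree from parallel vectors of
#' animal, sire and dam identifiers. Unknown parents are coded `0` (or `NA`)
#' on input and stored as `NA`. The returned object is a `data.frame` of class
#' `"pedigree"` with columns `id`, `sire`, `dam`, `year`, `sex` plus the
#' row-index columns `sire_row` and `dam_row` used by the recursions; rows are
#' ordered so that parents always precede their offspring.
#'
#' The sort is a stable topological sort keyed by (`year` if present, input
#' order), so the row order is deterministic for a given input.
#'
#' @param id integer vector of animal identifiers (unique, positive).
#' @param sire,dam integer vectors of parent identifiers; `0` or `NA` =
#'   unknown. A parent id never listed as an animal is inserted as a founder
#'   with a warning.
#' @param year optional integer vector of birth years.
#' @param sex optional character vector of sex codes (e.g. `"M"`/`"F"`). When
#'   supplied, an animal used both as a sire and as a dam raises an error.
#' @return an object of class `"pedigree"`.
#' @examples
#' ped <- pedigree(id = c(1, 2, 3, 4), sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 3))
#' ped
#' @export
pedigree <- function(id, sire, dam, year = NULL, sex = NULL) {
  id   <- as.integer(id)
  sire <- as.integer(sire)
  dam  <- as.integer(dam)
  n0 <- length(id)
  stopifnot(length(sire) == n0, length(dam) == n0)
  if (anyNA(id)) stop("animal ids must be non-missing integers")
  if (any(id <= 0L)) stop("animal ids must be positive integers")
  if (anyDuplicated(id)) {
    stop("duplicate animal_id: ", id[anyDuplicated(id)])
  }
  sire[is.na(sire)] <- 0L
  dam[is.na(dam)]   <- 0L
  if (!is.null(year)) {
    year <- as.integer(year)
    stopifnot(length(year) == n0)
  }
  if (!is.null(sex)) {
    sex <- as.character(sex)
    stopifnot(length(sex) == n0)
  }

  # auto-insert parents never defined as animals, as founders
  parents <- unique(c(sire[sire != 0L], dam[dam != 0L]))
  missing_par <- setdiff(parents, id)
  if (length(missing_par)) {
    warning("parent id(s) never defined as animals, inserted as founders: ",
            paste(sort(missing_par), collapse = ", "))
    id   <- c(id, missing_par)
    sire <- c(sire, rep(0L, length(missing_par)))
    dam  <- c(dam, rep(0L, length(missing_par)))
    if (!is.null(year)) year <- c(year, rep(NA_integer_, length(missing_par)))
    if (!is.null(sex))  sex  <- c(sex, rep(NA_character_, length(missing_par)))
  }
  n <- length(id)

  if (any(id == sire | id == dam)) {
    bad <- id[which(id == sire | id == dam)[1L]]
    stop("cycle detected in pedigree involving animal ", bad)
  }
  if (!is.null(sex)) {
    as_sire <- unique(sire[sire != 0L])
    as_dam  <- unique(dam[dam != 0L])
    both <- intersect(as_sire, as_dam)
    if (length(both)) {
      stop("sex-role conflict: animal(s) used as both sire and dam: ",
           paste(both, collapse = ", "))
    }
  }
  if (any(sire == dam & sire != 0L)) {
    warning("self-fertilization (sire == dam) present for animal(s): ",
            paste(id[sire == dam & sire != 0L], collapse = ", "))
  }

  ord <- .topo_sort(id, sire, dam, year)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  if (!is.null(year)) year <- year[ord]
  if (!is.null(sex)) sex <- sex[ord]

  pos <- match(id, id)  # identity, but gives the lookup template
  sire_row <- match(sire, id)
  dam_row  <- match(dam, id)
  ped <- data.frame(
    id = id, sire = ifelse(sire == 0L, NA_integer_, sire),
    dam = ifelse(dam == 0L, NA_integer_, dam),
    year = if (is.null(year)) NA_integer_ else year,
    sex = if (is.null(sex)) NA_character_ else sex,
    sire_row = sire_row, dam_row = dam_row,
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Stable topological sort: returns a permutation of seq_along(id) such that
# parents precede offspring; ties broken by (year, input order). Errors with
# the id of one animal on a cycle if no full order exists.
.topo_sort <- function(id, sire, dam, year = NULL) {
  n <- length(id)
  key <- if (is.null(year)) order(seq_len(n)) else order(year, seq_len(n), na.last = FALSE)
  placed <- logical(n)
  pos <- match(id, id)
  sire_row <- match(sire, id)  # NA when unknown
  dam_row  <- match(dam, id)
  out <- integer(n)
  k <- 0L
  pending <- key
  repeat {
    progress <- FALSE
    still <- integer(0)
    for (i in pending) {
      s <- sire_row[i]; d <- dam_row[i]
      ok <- (is.na(s) || placed[s]) && (is.na(d) || placed[d])
      if (ok) {
        k <- k + 1L
        out[k] <- i
        placed[i] <- TRUE
        progress <- TRUE
      } else {
        still <- c(still, i)
      }
    }
    if (!length(still)) break
    if (!progress) {
      stop("cycle detected in pedigree involving animal ", id[still[1L]])
    }
    pending <- still
  }
  out
}

#' Read a pedigree file
#'
#' Reads a plain delimited pedigree file with columns
#' `animal sire dam [year] [sex]`, unknown parents coded `0`. A header row is
#' auto-detected (non-numeric first field). Rows may appear in any order; the
#' result is topologically sorted so parents precede offspring.
#'
#' @param path path to the file.
#' @param delimiter field separator; `NULL` (default) auto-detects comma
#'   versus whitespace.
#' @return a [pedigree] object.
#' @export
read_pedigree <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", first, fixed = TRUE)) "," else ""
  }
  probe_fields <- strsplit(trimws(first),
                           if (delimiter == "") "[[:space:]]+" else delimiter)[[1L]]
  has_header <- suppressWarnings(is.na(as.numeric(probe_fields[1L])))
  df <- utils::read.table(path, sep = delimiter, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("pedigree file must have at least 3 columns")
  year <- if (ncol(df) >= 4L) df[[4L]] else NULL
  sex  <- if (ncol(df) >= 5L) df[[5L]] else NULL
  pedigree(df[[1L]], df[[2L]], df[[3L]], year = year, sex = sex)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire_row) & is.na(x$dam_row))
  cat(sprintf("pedigree: %d animals (%d founders)\n", nrow(x), nf))
  utils::head.matrix(as.data.frame(x)[, c("id", "sire", "dam", "year", "sex")],
                     n = 6L) |> print()
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write a pedigree to a delimited text file
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @param delimiter field separator (default one space).
#' @export
write_pedigree <- function(ped, path, delimiter = " ") {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(
    animal = ped$id,
    sire = ifelse(is.na(ped$sire), 0L, ped$sire),
    dam = ifelse(is.na(ped$dam), 0L, ped$dam)
  )
  if (!all(is.na(ped$year))) out$year <- ped$year
  if (!all(is.na(ped$sex)))  out$sex  <- ped$sex
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# number of known parents per animal, vectorized helper
.n_known_parents <- function(ped) {
  (!is.na(ped$sire_row)) + (!is.na(ped$dam_row))
}
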