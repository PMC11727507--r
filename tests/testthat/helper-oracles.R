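# Independent oracles -------------------------------------------------------
# These re-derive the package's quantities by routes that share no code with
# the implementation: gene-dropping Monte Carlo, dense per-ancestor tabular
# recursions, and dense multivariate-normal GLS/BLUP/likelihood algebra.

# Gene-dropping Monte Carlo estimate of total and partial inbreeding.
# Each founder allele is a unique label; every meiosis picks a parental slot
# at random. An identical-by-descent pair in animal j is traced up both
# lineages to the slot where they merge, then attributed to the ancestor
# whose Mendelian draw created the shared allele: at merge animal a whose
# shared slot came from parent l, the event belongs to a unless it is pushed
# up to l, which happens with probability (1 + IBD_l)/2 (IBD_l = the realized
# identity of l's own pair in that replicate); founder-original slots always
# stop. Returns per-pair counts / nrep.
gene_drop_partials <- function(ped, nrep = 1e5, seed = 1, chunk = 250000L) {
  sr <- ped$sire_row
  dr <- ped$dam_row
  n <- nrow(ped)
  counts <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  ibd_tot <- numeric(n)
  set.seed(seed)
  done <- 0L
  while (done < nrep) {
    m <- as.integer(min(chunk, nrep - done))
    pat <- matrix(0L, n, m)
    mat <- matrix(0L, n, m)
    srcp <- matrix(0L, n, m)  # 1 = parent's paternal slot, 2 = maternal, 0 = original
    srcm <- matrix(0L, n, m)
    for (j in seq_len(n)) {
      if (is.na(sr[j])) {
        pat[j, ] <- 2L * j - 1L
      } else {
        coin <- stats::runif(m) < 0.5
        pat[j, ] <- ifelse(coin, pat[sr[j], ], mat[sr[j], ])
        srcp[j, ] <- ifelse(coin, 1L, 2L)
      }
      if (is.na(dr[j])) {
        mat[j, ] <- 2L * j
      } else {
        coin <- stats::runif(m) < 0.5
        mat[j, ] <- ifelse(coin, pat[dr[j], ], mat[dr[j], ])
        srcm[j, ] <- ifelse(coin, 1L, 2L)
      }
    }
    ibd <- pat == mat
    ibd_tot <- ibd_tot + rowSums(ibd)
    lineage <- function(a, sl, r) {
      out <- integer(0)
      repeat {
        out <- c(out, 2L * a + sl)
        if (sl == 1L) {
          nxt <- sr[a]; nsl <- srcp[a, r]
        } else {
          nxt <- dr[a]; nsl <- srcm[a, r]
        }
        if (is.na(nxt) || nsl == 0L) return(list(codes = out, a = a, sl = sl))
        a <- nxt; sl <- nsl
      }
    }
    for (j in which(rowSums(ibd) > 0)) {
      if (is.na(sr[j]) || is.na(dr[j])) next
      for (r in which(ibd[j, ])) {
        l1 <- lineage(sr[j], srcp[j, r], r)
        # walk the dam-side lineage until it enters the sire-side one
        a <- dr[j]; sl <- srcm[j, r]
        while (!((2L * a + sl) %in% l1$codes)) {
          if (sl == 1L) {
            nxt <- sr[a]; nsl <- srcp[a, r]
          } else {
            nxt <- dr[a]; nsl <- srcm[a, r]
          }
          a <- nxt; sl <- nsl
        }
        # attribution chain upward from the merge slot
        repeat {
          par <- if (sl == 1L) sr[a] else dr[a]
          if (is.na(par)) break
          if (ibd[par, r] || stats::runif(1) < 0.5) {
            nsl <- if (sl == 1L) srcp[a, r] else srcm[a, r]
            a <- par; sl <- nsl
          } else break
        }
        counts[j, a] <- counts[j, a] + 1
      }
    }
    done <- done + m
  }
  list(F_hat = ibd_tot / nrep, partial_hat = counts / nrep, nrep = nrep)
}

# Dense per-ancestor tabular sweep: for every ancestor k, rerun the full
# tabular recursion with the Mendelian-variance matrix zeroed everywhere
# except phi_kk, and report F_j(k) = a^(k)(sire_j, dam_j) / 2. This is the
# unrestricted sweep; quadratic per ancestor, for small pedigrees only.
partials_dense_oracle <- function(ped, phi) {
  n <- nrow(ped)
  sr <- ped$sire_row
  dr <- ped$dam_row
  out <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (k in seq_len(n)) {
    A <- matrix(0, n, n)
    for (j in seq_len(n)) {
      if (j > 1L) {
        prev <- seq_len(j - 1L)
        row <- numeric(j - 1L)
        if (!is.na(sr[j])) row <- row + 0.5 * A[sr[j], prev]
        if (!is.na(dr[j])) row <- row + 0.5 * A[dr[j], prev]
        A[j, prev] <- row
        A[prev, j] <- row
      }
      # diagonal by the same recursion as the off-diagonals:
      # a(j,j) = (a(j,s) + a(j,d)) / 2 + phi_jk, with phi zero except at k
      dj <- 0
      if (!is.na(sr[j])) dj <- dj + 0.5 * A[j, sr[j]]
      if (!is.na(dr[j])) dj <- dj + 0.5 * A[j, dr[j]]
      A[j, j] <- dj + if (j == k) phi[k] else 0
    }
    for (j in seq_len(n)) {
      if (!is.na(sr[j]) && !is.na(dr[j])) {
        out[j, k] <- 0.5 * A[sr[j], dr[j]]
      }
    }
  }
  out
}

# Dense record-level design pieces mirroring the model definition (not the
# package's builder): intercept + drop-last-level dummies + f covariate.
dense_design <- function(ped, design, data, model = "FM") {
  n <- nrow(ped)
  arow <- match(data$animal_id, ped$id)
  nrec <- nrow(data)
  Zu <- matrix(0, nrec, n)
  Zu[cbind(seq_len(nrec), arow)] <- 1
  pe <- sort(unique(arow))
  Zp <- matrix(0, nrec, length(pe))
  Zp[cbind(seq_len(nrec), match(arow, pe))] <- 1
  v <- factor(data$fyp)
  keep <- levels(v)[-nlevels(v)]
  X <- cbind(1, outer(as.character(v), keep, "==") + 0, data$f)
  Zi <- if (model == "FM") Zu %*% as.matrix(design$K) else NULL
  list(X = X, Zu = Zu, Zi = Zi, Zp = Zp, y = data$y, arow = arow)
}

# Dense phenotypic covariance V under the model at given components.
dense_V <- function(ped, dd, vc, model = "FM") {
  A <- additive_relationship(ped)
  nrec <- length(dd$y)
  V <- vc$sigma_u2 * dd$Zu %*% A %*% t(dd$Zu) +
    vc$sigma_p2 * dd$Zp %*% t(dd$Zp) + diag(vc$sigma_e2, nrec)
  if (model == "FM") {
    V <- V + vc$sigma_i2 * dd$Zi %*% A %*% t(dd$Zi) +
      vc$sigma_ui * (dd$Zu %*% A %*% t(dd$Zi) + dd$Zi %*% A %*% t(dd$Zu))
  }
  V
}

# Dense GLS / BLUP solutions from V directly.
dense_blup <- function(ped, design, data, vc, model = "FM") {
  dd <- dense_design(ped, design, data, model)
  A <- additive_relationship(ped)
  V <- dense_V(ped, dd, vc, model)
  Vi <- solve(V)
  beta <- solve(t(dd$X) %*% Vi %*% dd$X, t(dd$X) %*% Vi %*% dd$y)
  resid <- dd$y - dd$X %*% beta
  Cu <- vc$sigma_u2 * A %*% t(dd$Zu)
  if (model == "FM") Cu <- Cu + vc$sigma_ui * A %*% t(dd$Zi)
  u <- Cu %*% Vi %*% resid
  i <- NULL
  if (model == "FM") {
    Ci <- vc$sigma_ui * A %*% t(dd$Zu) + vc$sigma_i2 * A %*% t(dd$Zi)
    i <- Ci %*% Vi %*% resid
  }
  list(beta = as.numeric(beta), u = as.numeric(u),
       i = if (is.null(i)) NULL else as.numeric(i))
}

# Dense restricted -2 log likelihood from V directly.
dense_m2ll <- function(ped, design, data, vc, model = "FM") {
  dd <- dense_design(ped, design, data, model)
  V <- dense_V(ped, dd, vc, model)
  Vi <- solve(V)
  XtViX <- t(dd$X) %*% Vi %*% dd$X
  beta <- solve(XtViX, t(dd$X) %*% Vi %*% dd$y)
  r <- dd$y - dd$X %*% beta
  (length(dd$y) - ncol(dd$X)) * log(2 * pi) +
    as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(XtViX)$modulus) +
    as.numeric(t(r) %*% Vi %*% r)
}
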