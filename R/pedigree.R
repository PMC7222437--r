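#' Pedigree container
#'
#' A validated, topologically sorted pedigree: parents always precede their
#' offspring in index order, unknown parents are coded `0`, and a logical
#' flag marks genotyped animals. All pedigree-derived sparse operators
#' (\eqn{A^{-1}}, ancestor blocks, \eqn{A_{gg}^{-1}}, \eqn{Q},
#' \eqn{\Delta}) are built from this object.
#'
#' @param sire,dam Integer vectors (length n) of parent indices; `0` (or
#'   `NA`) = unknown. Each known parent index must be smaller than the
#'   animal's own index.
#' @param genotyped Logical vector, length n.
#' @param original_id Labels carried through from the input file.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(sire, dam, genotyped = logical(length(sire)),
                     original_id = as.character(seq_along(sire))) {
  n <- length(sire)
  sire <- as.integer(sire); dam <- as.integer(dam)
  sire[is.na(sire)] <- 0L; dam[is.na(dam)] <- 0L
  genotyped <- as.logical(genotyped)
  stopifnot(length(dam) == n, length(genotyped) == n,
            length(original_id) == n)
  idx <- seq_len(n)
  if (any(sire < 0L | sire > n) || any(dam < 0L | dam > n))
    stop("parent id out of range")
  if (any(sire == idx) || any(dam == idx))
    stop("an animal cannot be its own parent")
  if (any(sire > idx) || any(dam > idx))
    stop("pedigree is not topologically sorted: parents must precede offspring")
  structure(list(n = n, sire = sire, dam = dam, genotyped = genotyped,
                 original_id = as.character(original_id)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d animals (%d genotyped, %d non-genotyped)\n",
              x$n, sum(x$genotyped), x$n - sum(x$genotyped)))
  invisible(x)
}

#' Read a pedigree file
#'
#' Delimited text with a header; columns `animal`, `sire`, `dam` and an
#' optional `genotyped` (0/1) column. `0` or `NA` marks an unknown parent.
#' Animals are renumbered to a topological order (Kahn's algorithm); the
#' original labels are kept in `original_id` and the mapping is returned
#' as attribute `id_map`.
#'
#' @param path File path.
#' @param sep Field separator (default: any whitespace).
#' @return A [pedigree]; `attr(, "id_map")` maps original label -> index.
#' @export
read_pedigree <- function(path, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns: animal, sire, dam")
  unknown <- function(v) is.na(v) | v %in% c("0", "", "NA", ".")
  ids <- df$animal
  if (anyDuplicated(ids)) stop("duplicated animal ids in pedigree file")
  lookup <- seq_along(ids); names(lookup) <- ids
  parent_idx <- function(v) {
    out <- integer(length(v))
    known <- !unknown(v)
    miss <- known & !(v %in% ids)
    if (any(miss))
      stop("parent id(s) absent from the animal column: ",
           paste(utils::head(v[miss], 5), collapse = ", "))
    out[known] <- lookup[v[known]]
    out
  }
  s <- parent_idx(df$sire); d <- parent_idx(df$dam)
  n <- length(ids)
  # Kahn topological sort on parent -> offspring edges
  indeg <- (s > 0L) + (d > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (s[i] > 0L) children[[s[i]]] <- c(children[[s[i]]], i)
    if (d[i] > 0L) children[[d[i]]] <- c(children[[d[i]]], i)
  }
  order_out <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    k <- k + 1L; order_out[k] <- v
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n) stop("pedigree contains a cycle (an animal is its own ancestor)")
  rank <- integer(n); rank[order_out] <- seq_len(n)
  geno <- if ("genotyped" %in% names(df))
    as.integer(df$genotyped) != 0L else logical(n)
  s2 <- integer(n); d2 <- integer(n); g2 <- logical(n); id2 <- character(n)
  for (i in seq_len(n)) {
    j <- rank[i]
    s2[j] <- if (s[i] > 0L) rank[s[i]] else 0L
    d2[j] <- if (d[i] > 0L) rank[d[i]] else 0L
    g2[j] <- geno[i]
    id2[j] <- ids[i]
  }
  ped <- pedigree(sire = s2, dam = d2, genotyped = g2, original_id = id2)
  map <- seq_len(n); names(map) <- id2
  attr(ped, "id_map") <- map
  ped
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' @param ped A [pedigree].
#' @return Numeric vector of inbreeding coefficients F.
#' @export
inbreeding_coefficients <- function(ped) {
  n <- ped$n; s <- ped$sire; d <- ped$dam
  f <- numeric(n)          # F_i
  L <- numeric(n)          # work: contribution of ancestor row
  Dvec <- numeric(n)       # within-family (Mendelian sampling) variances
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    Dvec[i] <- 0.5 - 0.25 * ((if (si > 0L) f[si] else -1) +
                             (if (di > 0L) f[di] else -1))
    if (si == 0L && di == 0L) { f[i] <- 0; next }
    # trace ancestors of i, accumulating L (column of the Cholesky of A)
    L[] <- 0; L[i] <- 1
    fi <- -1
    for (j in i:1) {
      if (L[j] == 0) next
      sj <- s[j]; dj <- d[j]
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * L[j]
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * L[j]
      fi <- fi + L[j]^2 * Dvec[j]
    }
    f[i] <- fi
  }
  f
}

# Mendelian-sampling precision alpha_i = 1/d_i per animal.
# Without inbreeding accounting: 2 (both parents known), 4/3 (one), 1 (none).
mendelian_alpha <- function(ped, account_inbreeding = FALSE) {
  s <- ped$sire; d <- ped$dam
  if (account_inbreeding) {
    f <- inbreeding_coefficients(ped)
    dv <- 0.5 - 0.25 * (ifelse(s > 0L, f[pmax(s, 1L)], -1) +
                        ifelse(d > 0L, f[pmax(d, 1L)], -1))
    1 / dv
  } else {
    np <- (s > 0L) + (d > 0L)
    c(1, 4 / 3, 2)[np + 1L]
  }
}

#' Build the sparse inverse numerator relationship matrix A^-1
#'
#' Henderson's recursive rules: each animal adds `alpha` to its own
#' diagonal, `-alpha/2` to the animal x parent entries, and `alpha/4` to
#' the parent x parent entries, with `alpha` = 2, 4/3 or 1 for two, one or
#' zero known parents (or inbreeding-corrected values when
#' `account_inbreeding = TRUE`). At most one diagonal and three
#' off-diagonal upper-triangle entries are touched per animal, hence the
#' `4n` bound on stored non-zeros.
#'
#' @param ped A [pedigree] (topologically sorted; validated at build).
#' @param account_inbreeding Use Meuwissen-Luo Mendelian-sampling variances.
#' @return Upper-triangular [crs3] of \eqn{A^{-1}}.
#' @export
build_a_inverse <- function(ped, account_inbreeding = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  a <- mendelian_alpha(ped, account_inbreeding)
  idx <- seq_len(n); s <- ped$sire; d <- ped$dam
  ks <- s > 0L; kd <- d > 0L; kb <- ks & kd
  ti <- c(idx,        idx[ks],      idx[kd],      s[ks],       d[kd],       s[kb])
  tj <- c(idx,        s[ks],        d[kd],        s[ks],       d[kd],       d[kb])
  tx <- c(a,          -a[ks] / 2,   -a[kd] / 2,   a[ks] / 4,   a[kd] / 4,   a[kb] / 4)
  crs3_from_triplets(ti, tj, tx, n)
}

#' Dense numerator relationship matrix A (tabular method)
#'
#' Independent of the Henderson-rule builder; intended for small pedigrees
#' (consistency checks, oracles, the `check` entry point).
#'
#' @param ped A [pedigree].
#' @return Dense n x n matrix A.
#' @export
dense_relationship_matrix <- function(ped) {
  n <- ped$n; s <- ped$sire; d <- ped$dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- 0.5 * ((if (si > 0L) A[prev, si] else 0) +
                  (if (di > 0L) A[prev, di] else 0))
      A[prev, i] <- v; A[i, prev] <- v
    }
    A[i, i] <- 1 + (if (si > 0L && di > 0L) 0.5 * A[si, di] else 0)
  }
  A
}

# Genotyped animals and all their ancestors (single backward pass; valid
# because parents precede offspring).
ancestor_closure <- function(ped) {
  inanc <- ped$genotyped
  for (i in ped$n:1) {
    if (inanc[i]) {
      if (ped$sire[i] > 0L) inanc[ped$sire[i]] <- TRUE
      if (ped$dam[i] > 0L) inanc[ped$dam[i]] <- TRUE
    }
  }
  inanc
}

#' Delta: A^{gg} minus its ancestor-pedigree counterpart
#'
#' The genotyped x genotyped contributions to \eqn{A^{-1}} of
#' non-genotyped offspring that are not ancestors of any genotyped animal,
#' read directly from the pedigree in one pass. Equals
#' \eqn{A^{gg} - A^{gg}_{anc}} exactly.
#'
#' @param ped A [pedigree].
#' @param account_inbreeding Match the main \eqn{A^{-1}} build.
#' @return [crs3] of order `n_g` (number of genotyped animals).
#' @export
build_delta <- function(ped, account_inbreeding = FALSE) {
  g <- ped$genotyped
  n_g <- sum(g)
  grank <- integer(ped$n); grank[g] <- seq_len(n_g)
  inanc <- ancestor_closure(ped)
  a <- mendelian_alpha(ped, account_inbreeding)
  out <- which(!inanc)                    # never genotyped, never an ancestor
  s <- ped$sire[out]; d <- ped$dam[out]; av <- a[out]
  ks <- s > 0L & g[pmax(s, 1L)]
  kd <- d > 0L & g[pmax(d, 1L)]
  kb <- ks & kd
  ti <- c(grank[s[ks]], grank[d[kd]], grank[s[kb]])
  tj <- c(grank[s[ks]], grank[d[kd]], grank[d[kb]])
  tx <- c(av[ks] / 4, av[kd] / 4, av[kb] / 4)
  if (!length(ti))
    return(crs3(ia = rep(1L, n_g + 1L), ja = integer(0), aa = numeric(0),
                n_rows = n_g))
  crs3_from_triplets(ti, tj, tx, n_g)
}

#' Pedigree operators for the single-step systems
#'
#' Builds everything the matrix-free systems need from the pedigree:
#' the full \eqn{A^{-1}} in CRS3, its g/n partition as sparse blocks, the
#' ancestor-restricted inverse split into gg/gn/nn blocks with a sparse
#' Cholesky factorization of \eqn{A^{nn}_{anc}}, and \eqn{\Delta}. The
#' operators \eqn{A_{gg}^{-1} = A^{gg}_{anc} - A^{gn}_{anc}
#' (A^{nn}_{anc})^{-1} A^{ng}_{anc}} and \eqn{Q = A^{gn}_{anc}
#' (A^{nn}_{anc})^{-1} A^{ng}_{anc} + \Delta} are then applied matrix-free
#' via [agg_inv_matmat()] and [q_matmat()].
#'
#' @param ped A [pedigree] with at least one genotyped animal.
#' @param account_inbreeding Inbreeding-corrected Mendelian variances.
#' @return An object of class `pedigree_operators`.
#' @export
extract_ancestor_blocks <- function(ped, account_inbreeding = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  g <- ped$genotyped
  if (!any(g)) stop("no genotyped animals in the pedigree")
  a_inv_full <- build_a_inverse(ped, account_inbreeding)
  Afull <- as(crs3_to_dsc(a_inv_full), "generalMatrix")   # dgC, both triangles
  gi <- which(g); ni <- which(!g)
  Ann <- Afull[ni, ni, drop = FALSE]
  Ang <- Afull[ni, gi, drop = FALSE]
  Agg <- Afull[gi, gi, drop = FALSE]
  # ancestor-restricted pedigree: closed under taking parents, so parent
  # links survive the restriction unchanged (and so do Mendelian alphas)
  inanc <- ancestor_closure(ped)
  anc <- which(inanc)
  arank <- integer(ped$n); arank[anc] <- seq_along(anc)
  ped_anc <- pedigree(
    sire = ifelse(ped$sire[anc] > 0L, arank[pmax(ped$sire[anc], 1L)], 0L),
    dam  = ifelse(ped$dam[anc] > 0L, arank[pmax(ped$dam[anc], 1L)], 0L),
    genotyped = ped$genotyped[anc],
    original_id = ped$original_id[anc])
  a_inv_anc <- build_a_inverse(ped_anc, account_inbreeding)
  Aanc <- as(crs3_to_dsc(a_inv_anc), "generalMatrix")
  gia <- which(ped_anc$genotyped); nia <- which(!ped_anc$genotyped)
  a_gg_anc <- Aanc[gia, gia, drop = FALSE]
  a_gn_anc <- Aanc[gia, nia, drop = FALSE]
  a_nn_anc <- Aanc[nia, nia, drop = FALSE]
  solver_nn_anc <- if (length(nia))
    Matrix::Cholesky(Matrix::forceSymmetric(a_nn_anc), LDL = FALSE,
                     perm = TRUE) else NULL
  delta <- build_delta(ped, account_inbreeding)
  structure(list(
    ped = ped, account_inbreeding = account_inbreeding,
    a_inv_full = a_inv_full,
    Ann = Ann, Ang = Ang, Agn = Matrix::t(Ang), Agg = Agg,
    anc_index = anc,
    a_gg_anc = a_gg_anc, a_gn_anc = a_gn_anc, a_nn_anc = a_nn_anc,
    solver_nn_anc = solver_nn_anc,
    delta = delta,
    g_index = gi, n_index = ni,
    n = ped$n, n_g = length(gi), n_n = length(ni)
  ), class = "pedigree_operators")
}

#' @export
print.pedigree_operators <- function(x, ...) {
  cat(sprintf("Pedigree operators: n = %d, n_g = %d, n_n = %d, ancestors of genotyped = %d\n",
              x$n, x$n_g, x$n_n, length(x$anc_index)))
  cat(sprintf("  A^-1: %d stored non-zeros (upper), %s bytes (bound %s)\n",
              crs3_nnz(x$a_inv_full),
              format(crs3_bytes(x$n, crs3_nnz(x$a_inv_full)), big.mark = ","),
              format(crs3_ainv_bound_bytes(x$n), big.mark = ",")))
  invisible(x)
}

as_col_matrix <- function(v, n) {
  if (is.null(dim(v))) matrix(as.numeric(v), nrow = n) else as.matrix(v) * 1.0
}

#' Apply Q to a matrix of genotyped-animal columns
#'
#' \eqn{Q V = A^{gn}_{anc} (A^{nn}_{anc})^{-1} A^{ng}_{anc} V + \Delta V},
#' costing one sparse triangular solve against the cached factorization of
#' \eqn{A^{nn}_{anc}} per column. Callers that need several Q products per
#' iteration (the Mantysaari-Stranden matvec needs two) batch the columns.
#'
#' @param ops [extract_ancestor_blocks()] output.
#' @param v Numeric vector/matrix with `n_g` rows.
#' @return `Q %*% v`, dense.
#' @export
q_matmat <- function(ops, v) {
  vm <- as_col_matrix(v, ops$n_g)
  was_vec <- is.null(dim(v))
  out <- crs3_matmat(ops$delta, vm)
  if (!is.null(ops$solver_nn_anc)) {
    t1 <- Matrix::t(ops$a_gn_anc) %*% vm              # A^ng_anc V
    t2 <- Matrix::solve(ops$solver_nn_anc, t1, system = "A")
    out <- out + as.matrix(ops$a_gn_anc %*% t2)
  }
  if (was_vec) drop(out) else out
}

#' Apply A_gg^-1 (inverse of the genotyped-animal block of A) to a matrix
#'
#' \eqn{A_{gg}^{-1} V = A^{gg}_{anc} V - A^{gn}_{anc} (A^{nn}_{anc})^{-1}
#' A^{ng}_{anc} V}; note \eqn{A_{gg}^{-1} = A^{gg} - Q}.
#'
#' @inheritParams q_matmat
#' @export
agg_inv_matmat <- function(ops, v) {
  vm <- as_col_matrix(v, ops$n_g)
  was_vec <- is.null(dim(v))
  out <- as.matrix(ops$a_gg_anc %*% vm)
  if (!is.null(ops$solver_nn_anc)) {
    t1 <- Matrix::t(ops$a_gn_anc) %*% vm
    t2 <- Matrix::solve(ops$solver_nn_anc, t1, system = "A")
    out <- out - as.matrix(ops$a_gn_anc %*% t2)
  }
  if (was_vec) drop(out) else out
}

#' Monte-Carlo estimate of diag(A_gg^-1)
#'
#' Hutchinson's stochastic diagonal estimator with Rademacher probes:
#' \eqn{\widehat{diag} = s^{-1} \sum_k (A_{gg}^{-1} z_k) \circ z_k} with
#' independent +-1 vectors \eqn{z_k}. Exact for a 1 x 1 block, unbiased in
#' general; 1000 samples is the routine-evaluation default.
#'
#' @param ops [extract_ancestor_blocks()] output.
#' @param n_samples Number of probe vectors (>= 1).
#' @param seed RNG seed; the estimate is bitwise reproducible given it.
#' @param batch Columns per batched solve.
#' @return Numeric vector, length `n_g`.
#' @export
mc_diag_agg_inverse <- function(ops, n_samples = 1000, seed = 1,
                                batch = 256L) {
  stopifnot(n_samples >= 1)
  with_seed(seed, {
    acc <- numeric(ops$n_g)
    done <- 0L
    while (done < n_samples) {
      nb <- min(batch, n_samples - done)
      z <- matrix(sample(c(-1, 1), ops$n_g * nb, replace = TRUE),
                  nrow = ops$n_g)
      acc <- acc + rowSums(agg_inv_matmat(ops, z) * z)
      done <- done + nb
    }
    acc / n_samples
  })
}

#' Count pedigree links whose parent is genotyped
#'
#' `n_offspring` for the SNP-block preconditioner approximation
#' \eqn{(2 n_g + n_{offspring}) p_j (1 - p_j)}. By default an offspring of
#' two genotyped parents counts twice (parent-link convention);
#' `distinct = TRUE` switches to counting distinct offspring. The
#' preconditioner tolerates either convention.
#'
#' @param ped A [pedigree].
#' @param distinct Count distinct offspring instead of parent links.
#' @return Integer count.
#' @export
count_genotyped_parent_links <- function(ped, distinct = FALSE) {
  g <- ped$genotyped
  sg <- ped$sire > 0L & g[pmax(ped$sire, 1L)]
  dg <- ped$dam > 0L & g[pmax(ped$dam, 1L)]
  if (distinct) sum(sg | dg) else sum(sg) + sum(dg)
}
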