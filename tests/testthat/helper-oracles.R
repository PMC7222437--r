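# Independent dense oracles: everything here is built with base R from the
# printed block formulas (tabular relationship matrix, dense inverses,
# dense centered genotypes, explicit incidence matrices), never through the
# package's sparse / matrix-free routes.

# tabular (recursive) numerator relationship matrix
tab_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- 0.5 * ((if (s > 0L) A[prev, s] else 0) +
                  (if (d > 0L) A[prev, d] else 0))
      A[prev, i] <- v; A[i, prev] <- v
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  A
}

# random topologically sorted pedigree with a genotyped subset
rand_ped <- function(n, geno_frac = 0.3, founder_frac = 0.2, seed = 1) {
  set.seed(seed)
  sire <- integer(n); dam <- integer(n)
  nf <- max(2L, round(n * founder_frac))
  for (i in (nf + 1L):n) {
    pool <- seq_len(i - 1L)
    if (stats::runif(1) < 0.85) sire[i] <- sample(pool, 1L)
    if (stats::runif(1) < 0.85) {
      d <- sample(pool, 1L)
      if (d != sire[i]) dam[i] <- d
    }
  }
  genotyped <- stats::runif(n) < geno_frac
  if (!any(genotyped)) genotyped[n] <- TRUE
  pedigree(sire = sire, dam = dam, genotyped = genotyped)
}

# dense centered Z and frequencies from an integer dosage matrix (NA missing)
dense_center <- function(dosages) {
  p <- apply(dosages, 2L, function(col) {
    obs <- col[!is.na(col)]
    sum(obs) / (2 * length(obs))
  })
  Z <- sweep(dosages, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  list(Z = Z, p = p, m = 2 * sum(p * (1 - p)))
}

# Dense assembly of either single-step system from the printed block
# formulas. `rec` is a record_set; `dosages` the genotyped-subset dosage
# matrix in pedigree order of genotyped animals.
dense_oracle <- function(spec, rec, ped, dosages, variant) {
  n <- ped$n; g <- ped$genotyped
  gi <- which(g); ni <- which(!g)
  n_g <- length(gi); n_n <- length(ni)
  q <- spec$q; nt <- length(spec$traits); ntypes <- spec$ntypes
  w <- spec$w
  Gi <- solve(spec$G0)
  A <- tab_A(ped$sire, ped$dam)
  Ainv <- solve(A)
  Ann <- Ainv[ni, ni, drop = FALSE]; Ang <- Ainv[ni, gi, drop = FALSE]
  Agg <- Ainv[gi, gi, drop = FALSE]
  AggInv <- solve(A[gi, gi, drop = FALSE])
  Qd <- if (n_n) t(Ang) %*% solve(Ann, Ang) else matrix(0, n_g, n_g)
  zc <- dense_center(dosages)
  Zd <- zc$Z; m <- zc$m; nsnp <- ncol(Zd)

  # fixed columns: all levels of the large effect, first level dropped
  # elsewhere; then user covariates; then one J covariate per channel
  nlev <- vapply(rec$fixed, nlevels, 0L)
  large <- spec$large_fixed
  if (is.null(large) && length(spec$fixed_class))
    large <- spec$fixed_class[which.max(nlev)]
  Fm <- NULL
  for (e in spec$fixed_class) {
    mm <- stats::model.matrix(~ f - 1, data.frame(f = rec$fixed[[e]]))
    if (!identical(e, large) && ncol(mm) > 1L) mm <- mm[, -1L, drop = FALSE]
    Fm <- cbind(Fm, mm)
  }
  if (ncol(rec$covar)) Fm <- cbind(Fm, rec$covar)
  if (spec$j_covariates) {
    j <- numeric(n); j[gi] <- -1
    if (n_n) j[ni] <- solve(Ann, Ang %*% rep(1, n_g))
    for (tt in seq_len(nt)) for (ty in seq_len(ntypes)) {
      an <- if (ty == 1L) rec$animal else rec$dam
      col <- ifelse(rec$trait == tt & an > 0L, j[pmax(an, 1L)], 0)
      Fm <- cbind(Fm, col)
    }
  }
  Fm <- if (is.null(Fm)) matrix(0, rec$n, 0) else as.matrix(Fm)
  nf <- ncol(Fm)

  pe_levels <- if (spec$pe) sort(unique(rec$dam[rec$dam > 0L])) else integer(0)
  npe <- length(pe_levels)
  Hpe <- matrix(0, rec$n, npe * nt)
  if (npe) for (r in seq_len(rec$n)) if (rec$dam[r] > 0L) {
    l <- match(rec$dam[r], pe_levels)
    Hpe[r, (l - 1L) * nt + rec$trait[r]] <- 1
  }
  # genetic incidence over all animals, channel fastest within animal
  Hu <- matrix(0, rec$n, n * q)
  for (r in seq_len(rec$n)) {
    tt <- rec$trait[r]
    Hu[r, (rec$animal[r] - 1L) * q + (tt - 1L) * ntypes + 1L] <- 1
    if (ntypes == 2L && rec$dam[r] > 0L)
      Hu[r, (rec$dam[r] - 1L) * q + (tt - 1L) * ntypes + 2L] <- 1
  }
  chans <- function(idx) as.vector(vapply(idx, function(i)
    (i - 1L) * q + seq_len(q), integer(q)))
  Hun <- Hu[, chans(ni), drop = FALSE]
  Hag <- Hu[, chans(gi), drop = FALSE]
  rinv <- 1 / diag(spec$R0)[rec$trait]
  xpx <- function(Hl, Hr) t(Hl) %*% (rinv * Hr)
  kronq <- function(S) kronecker(S, Gi)
  pe_prior <- if (npe) kronecker(diag(npe), solve(spec$P0)) else
    matrix(0, 0, 0)

  if (variant == "ms") {
    Hsnp <- Hag %*% kronecker(Zd, diag(q))
    H <- cbind(Fm, Hpe, Hun, Hag, Hsnp)
    C <- xpx(H, H)
    off <- nf + npe * nt
    iu <- off + seq_len(n_n * q)
    ia <- off + n_n * q + seq_len(n_g * q)
    ig <- off + (n_n + n_g) * q + seq_len(nsnp * q)
    if (npe) {
      ip <- nf + seq_len(npe * nt)
      C[ip, ip] <- C[ip, ip] + pe_prior
    }
    if (n_n) {
      C[iu, iu] <- C[iu, iu] + kronq(Ann)
      C[iu, ia] <- C[iu, ia] + kronq(Ang)
      C[ia, iu] <- C[ia, iu] + kronq(t(Ang))
      C[iu, ig] <- C[iu, ig] + kronq(Ang %*% Zd)
      C[ig, iu] <- C[ig, iu] + kronq(t(Ang %*% Zd))
    }
    C[ia, ia] <- C[ia, ia] + kronq(Agg / w + (1 - 1 / w) * Qd)
    C[ia, ig] <- C[ia, ig] + kronq(Qd %*% Zd)
    C[ig, ia] <- C[ig, ia] + kronq(t(Qd %*% Zd))
    C[ig, ig] <- C[ig, ig] + kronq(t(Zd) %*% Qd %*% Zd +
                                     m / (1 - w) * diag(nsnp))
    b <- as.numeric(t(H) %*% (rinv * rec$y))
  } else {
    H <- cbind(Fm, Hpe, Hun, Hag)
    Cls <- xpx(H, H)
    tot <- ncol(H) + nsnp * q
    C <- matrix(0, tot, tot)
    C[seq_len(ncol(H)), seq_len(ncol(H))] <- Cls
    off <- nf + npe * nt
    iu <- off + seq_len(n_n * q)
    ia <- off + n_n * q + seq_len(n_g * q)
    ig <- off + (n_n + n_g) * q + seq_len(nsnp * q)
    if (npe) {
      ip <- nf + seq_len(npe * nt)
      C[ip, ip] <- C[ip, ip] + pe_prior
    }
    if (n_n) {
      C[iu, iu] <- C[iu, iu] + kronq(Ann)
      C[iu, ia] <- C[iu, ia] + kronq(Ang)
      C[ia, iu] <- C[ia, iu] + kronq(t(Ang))
    }
    C[ia, ia] <- C[ia, ia] + kronq(Agg + (1 / w - 1) * AggInv)
    C[ia, ig] <- C[ia, ig] + kronq(-(1 / w) * AggInv %*% Zd)
    C[ig, ia] <- C[ig, ia] + kronq(t(-(1 / w) * AggInv %*% Zd))
    C[ig, ig] <- C[ig, ig] + kronq((1 / w) * t(Zd) %*% AggInv %*% Zd +
                                     m / (1 - w) * diag(nsnp))
    b <- c(as.numeric(t(H) %*% (rinv * rec$y)), numeric(nsnp * q))
  }
  list(C = C, b = b, A = A, Ainv = Ainv, AggInv = AggInv, Q = Qd, Z = Zd,
       m = m, nf = nf, off_un = nf + npe * nt,
       off_ag = nf + npe * nt + n_n * q,
       off_g = nf + npe * nt + (n_n + n_g) * q)
}

# dense pedigree-BLUP of the same model (no SNP equations): the w -> 1 limit
dense_pedigree_blup <- function(spec, rec, ped, dosages) {
  n <- ped$n; q <- spec$q; nt <- length(spec$traits); ntypes <- spec$ntypes
  gi <- which(ped$genotyped); ni <- which(!ped$genotyped)
  Gi <- solve(spec$G0)
  A <- tab_A(ped$sire, ped$dam)
  Ainv <- solve(A)
  # reuse the oracle's fixed/pe/genetic design by asking for the Liu system
  # and dropping its SNP equations is not possible (AggInv couples them), so
  # rebuild the plain animal-model normal equations directly
  or <- dense_oracle(spec, rec, ped, dosages, "liu")  # for Fm layout only
  nf <- or$nf
  pe_levels <- if (spec$pe) sort(unique(rec$dam[rec$dam > 0L])) else integer(0)
  npe <- length(pe_levels)
  # recreate designs exactly as the oracle does
  nlev <- vapply(rec$fixed, nlevels, 0L)
  large <- spec$large_fixed
  if (is.null(large) && length(spec$fixed_class))
    large <- spec$fixed_class[which.max(nlev)]
  Fm <- NULL
  for (e in spec$fixed_class) {
    mm <- stats::model.matrix(~ f - 1, data.frame(f = rec$fixed[[e]]))
    if (!identical(e, large) && ncol(mm) > 1L) mm <- mm[, -1L, drop = FALSE]
    Fm <- cbind(Fm, mm)
  }
  if (ncol(rec$covar)) Fm <- cbind(Fm, rec$covar)
  if (spec$j_covariates) {
    j <- numeric(n); j[gi] <- -1
    if (length(ni)) {
      Ann <- Ainv[ni, ni, drop = FALSE]; Ang <- Ainv[ni, gi, drop = FALSE]
      j[ni] <- solve(Ann, Ang %*% rep(1, length(gi)))
    }
    for (tt in seq_len(nt)) for (ty in seq_len(ntypes)) {
      an <- if (ty == 1L) rec$animal else rec$dam
      Fm <- cbind(Fm, ifelse(rec$trait == tt & an > 0L, j[pmax(an, 1L)], 0))
    }
  }
  Fm <- as.matrix(Fm)
  Hpe <- matrix(0, rec$n, npe * nt)
  if (npe) for (r in seq_len(rec$n)) if (rec$dam[r] > 0L) {
    l <- match(rec$dam[r], pe_levels)
    Hpe[r, (l - 1L) * nt + rec$trait[r]] <- 1
  }
  Hu <- matrix(0, rec$n, n * q)
  for (r in seq_len(rec$n)) {
    tt <- rec$trait[r]
    Hu[r, (rec$animal[r] - 1L) * q + (tt - 1L) * ntypes + 1L] <- 1
    if (ntypes == 2L && rec$dam[r] > 0L)
      Hu[r, (rec$dam[r] - 1L) * q + (tt - 1L) * ntypes + 2L] <- 1
  }
  H <- cbind(Fm, Hpe, Hu)
  rinv <- 1 / diag(spec$R0)[rec$trait]
  C <- t(H) %*% (rinv * H)
  iu <- ncol(Fm) + npe * nt + seq_len(n * q)
  C[iu, iu] <- C[iu, iu] + kronecker(Ainv, Gi)
  if (npe) {
    ip <- ncol(Fm) + seq_len(npe * nt)
    C[ip, ip] <- C[ip, ip] + kronecker(diag(npe), solve(spec$P0))
  }
  b <- as.numeric(t(H) %*% (rinv * rec$y))
  x <- solve(C, b)
  u <- t(matrix(x[iu], nrow = q))   # n x q
  list(x = x, u = u, nf = ncol(Fm), npe = npe)
}

# memoised tiny simulated datasets shared across test files
.fixture_env <- new.env(parent = emptyenv())
tiny_dataset <- function(key = "default", ...) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  args <- list(...)
  cfg <- do.call(sim_config, args)
  ds <- simulate_dataset(cfg)
  ds$ops <- extract_ancestor_blocks(ds$ped)
  ds$rs <- record_set(ds$records, ds$spec, ds$ped)
  .fixture_env[[key]] <- ds
  ds
}

tiny_bivariate <- function() tiny_dataset(
  "bivar",
  n_founders = 24L, n_generations = 3L, offspring_per_mating = 2L,
  n_snp = 30L, genotyping_rate = c(0, 0.25, 0.4, 0.6),
  fixed_levels = c(hys = 4L, ym = 3L), fixed_sd = c(hys = 1, ym = 0.5),
  missing_rate = 0.02, seed = 101L)

# dense coefficient matrix of an assembled system via unit vectors
# (implementation route; used where the comparison target is the oracle)
dense_from_matvec <- function(sys) {
  n <- sys$map$total
  vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    system_matvec(sys, e)
  }, numeric(n))
}
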