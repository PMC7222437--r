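#' Model specification for a single-step SNP-BLUP analysis
#'
#' Defines the traits, the genetic channels (direct and, optionally,
#' maternal, per trait), the fixed structure, the optional permanent
#' environment effect of the dam, and the variance components. With
#' `q = traits x types` genetic channels, the scalar additive variance of
#' the univariate system generalises to the q x q matrix `G0`; every
#' occurrence of \eqn{\sigma_u^{-2}} in the system becomes a Kronecker
#' product with `G0^{-1}`, with channels ordered fastest within a level.
#'
#' @param traits Character vector of trait names. Each record carries
#'   exactly one observed trait.
#' @param maternal Add a maternal genetic channel per trait (the dam's
#'   genotype/pedigree effect expressed in the offspring's record).
#' @param fixed_class Names of fixed cross-classified effects (columns of
#'   the record table). One of them is the designated "large" effect that
#'   gets a purely diagonal preconditioner block.
#' @param large_fixed Name of the designated large fixed effect; default
#'   is the class effect with the most observed levels.
#' @param covariates Names of numeric covariate columns.
#' @param j_covariates Fit one J covariate per genetic channel (pedigree-
#'   genomic compatibility): `j = -1` on genotyped animals and
#'   `A^{nn} j_n = -A^{ng} j_g` on non-genotyped ones. Default `TRUE`.
#' @param pe Fit a permanent environment effect of the dam (one channel
#'   per trait, covariance `P0`).
#' @param G0 q x q genetic covariance matrix (scalar allowed when q = 1).
#' @param R0 Residual covariance; only the per-trait variances (diagonal)
#'   are used, as each record observes a single trait.
#' @param P0 Permanent environment covariance (traits x traits) when
#'   `pe = TRUE`.
#' @param w Residual polygenic fraction, strictly in (0, 1): the share of
#'   additive genetic variance modelled through the pedigree rather than
#'   the SNPs. Default 0.05, the routine-evaluation value.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(traits, maternal = FALSE,
                       fixed_class = character(), large_fixed = NULL,
                       covariates = character(), j_covariates = TRUE,
                       pe = FALSE, G0, R0, P0 = NULL, w = 0.05) {
  traits <- as.character(traits)
  fixed_class <- as.character(fixed_class)
  covariates <- as.character(covariates)
  nt <- length(traits)
  ntypes <- if (maternal) 2L else 1L
  q <- nt * ntypes
  if (is.null(dim(G0))) G0 <- diag(as.numeric(G0), q)
  G0 <- as.matrix(G0)
  if (is.null(dim(R0))) R0 <- diag(as.numeric(R0), nt)
  R0 <- as.matrix(R0)
  if (!is.null(P0) && is.null(dim(P0))) P0 <- diag(as.numeric(P0), nt)
  if (!(is.numeric(w) && length(w) == 1 && w > 0 && w < 1))
    stop("w must be strictly between 0 and 1")
  if (nrow(G0) != q) stop("G0 must be ", q, " x ", q)
  if (!is_spd(G0)) stop("G0 must be symmetric positive definite")
  if (nrow(R0) != nt || !is_spd(R0))
    stop("R0 must be a symmetric positive definite ", nt, " x ", nt, " matrix")
  if (pe) {
    if (is.null(P0)) stop("pe = TRUE requires P0")
    if (nrow(P0) != nt || !is_spd(as.matrix(P0)))
      stop("P0 must be symmetric positive definite ", nt, " x ", nt)
  }
  if (!is.null(large_fixed) && !(large_fixed %in% fixed_class))
    stop("large_fixed must be one of fixed_class")
  type_names <- if (maternal) c("direct", "maternal") else "direct"
  channels <- as.vector(t(outer(traits, type_names, paste, sep = ":")))
  structure(list(traits = traits, maternal = maternal, ntypes = ntypes,
                 q = q, channels = channels,
                 fixed_class = fixed_class, large_fixed = large_fixed,
                 covariates = covariates, j_covariates = j_covariates,
                 pe = pe, G0 = G0, R0 = as.matrix(R0),
                 P0 = if (pe) as.matrix(P0) else NULL, w = w),
            class = "model_spec")
}

#' Build a validated record set
#'
#' @param df Data frame with columns `trait`, `y`, `animal`, optionally
#'   `dam`, plus the fixed-effect and covariate columns named in the
#'   model. `animal`/`dam` may be pedigree indices (integer) or original
#'   ids (character; mapped through the pedigree). `dam = 0`/`NA` means
#'   unknown: the maternal and permanent environment terms are omitted
#'   for that record.
#' @param spec A [model_spec].
#' @param ped The [pedigree] the records refer to.
#' @return An object of class `record_set`.
#' @export
record_set <- function(df, spec, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "pedigree"))
  need <- c("trait", "y", "animal", spec$fixed_class, spec$covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("record table lacks column(s): ",
                         paste(miss, collapse = ", "))
  keep <- !is.na(df$y)
  if (!all(keep)) {
    message(sum(!keep), " record(s) with missing response dropped")
    df <- df[keep, , drop = FALSE]
  }
  trait <- match(as.character(df$trait), spec$traits)
  if (anyNA(trait)) stop("record trait(s) not in the model: ",
                         paste(unique(df$trait[is.na(trait)]), collapse = ", "))
  map_animal <- function(v, allow_zero) {
    if (is.numeric(v)) {
      v <- as.integer(v)
      if (any(v < 0L | v > ped$n) || (!allow_zero && any(v == 0L)))
        stop("record animal index out of pedigree range")
      return(v)
    }
    v <- as.character(v)
    out <- match(v, ped$original_id)
    unknown <- v %in% c("0", "", "NA", ".")
    if (allow_zero) out[unknown] <- 0L
    if (anyNA(out))
      stop("record animal id(s) absent from the pedigree: ",
           paste(utils::head(unique(v[is.na(out)]), 5), collapse = ", "))
    out
  }
  animal <- map_animal(df$animal, allow_zero = FALSE)
  dam <- if ("dam" %in% names(df)) map_animal(df$dam, allow_zero = TRUE)
         else ped$dam[animal]
  fixed <- lapply(spec$fixed_class, function(e) factor(df[[e]]))
  names(fixed) <- spec$fixed_class
  covar <- if (length(spec$covariates))
    as.matrix(df[spec$covariates]) * 1.0 else
    matrix(0, nrow(df), 0)
  structure(list(n = nrow(df), trait = trait, y = as.numeric(df$y),
                 animal = animal, dam = dam, fixed = fixed, covar = covar),
            class = "record_set")
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("Record set: %d records, %d trait(s)\n", x$n,
              length(unique(x$trait))))
  invisible(x)
}

#' J covariates for pedigree-genomic compatibility
#'
#' One vector over all animals, fitted as a fixed covariate on each
#' genetic channel's incidence: `j = -1` for genotyped animals, and the
#' non-genotyped part solves `A^{nn} j_n = -A^{ng} j_g` (full-pedigree
#' blocks of \eqn{A^{-1}}).
#'
#' @param ped_ops [extract_ancestor_blocks()] output.
#' @return Numeric vector of length `n` (all animals).
#' @export
j_covariates <- function(ped_ops) {
  j <- numeric(ped_ops$n)
  j[ped_ops$g_index] <- -1
  if (ped_ops$n_n > 0) {
    rhs <- ped_ops$Ang %*% rep(1, ped_ops$n_g)  # = -A^ng j_g
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(ped_ops$Ann),
                           LDL = FALSE, perm = TRUE)
    j[ped_ops$n_index] <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  }
  j
}

# channel index of (trait t, type k) with channels fastest within level
channel_of <- function(spec, t, type) (t - 1L) * spec$ntypes + type

# n x q matrix view of a channel-fastest block vector, and back
blk_mat <- function(x, q) t(matrix(x, nrow = q))
blk_vec <- function(m) as.vector(t(m))

#' Assemble a single-step SNP-BLUP system as a split matrix-free operator
#'
#' Builds the least-squares part as one in-memory sparse matrix over
#' `[fixed | permanent environment | u_n | a_g (or u_g) | duplicate
#' genotyped channel]` (the duplicate channel carries `Z g` products so
#' that records on genotyped animals load on both the residual polygenic
#' and the SNP equations), the right-hand side, and everything the
#' pedigree/genotype parts of the coefficient matrix need. The full
#' operator is only ever applied through [system_matvec()]:
#' `C_MS = T'(C_LS + C_R1)T + C_R2` and
#' `C_Liu = C_LS + T'C_R1 T + C_R2`, with `T` the identity except for the
#' SNP block, which it maps through Z.
#'
#' @param spec A [model_spec].
#' @param records A [record_set].
#' @param ped_ops [extract_ancestor_blocks()] output for the same pedigree.
#' @param geno A [packed_genotypes] whose animals match the pedigree's
#'   genotyped animals (any order; reordered internally if needed).
#' @param cinfo [allele_frequencies()] of `geno` (computed if `NULL`).
#' @param variant `"liu"` or `"ms"`.
#' @return An object of class `ssnpblup_system` with the right-hand side
#'   in `$b` and an equation index map in `$map`.
#' @export
assemble_system <- function(spec, records, ped_ops, geno, cinfo = NULL,
                            variant = c("liu", "ms")) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "model_spec"), inherits(records, "record_set"),
            inherits(ped_ops, "pedigree_operators"),
            inherits(geno, "packed_genotypes"))
  ped <- ped_ops$ped
  # align genotype store with pedigree order of genotyped animals
  want <- ped$original_id[ped_ops$g_index]
  if (!identical(geno$animal_ids, want)) {
    perm <- match(want, geno$animal_ids)
    if (anyNA(perm))
      stop("genotyped pedigree animal(s) absent from the genotype file: ",
           paste(utils::head(want[is.na(perm)], 5), collapse = ", "))
    geno <- reorder_genotypes(geno, perm)
  }
  if (is.null(cinfo)) cinfo <- allele_frequencies(geno)
  q <- spec$q; nt <- length(spec$traits); ntypes <- spec$ntypes
  n_n <- ped_ops$n_n; n_g <- ped_ops$n_g; n_snp <- geno$n_snp
  grank <- integer(ped$n); grank[ped_ops$g_index] <- seq_len(n_g)
  nrank <- integer(ped$n); nrank[ped_ops$n_index] <- seq_len(n_n)

  # ---- fixed-effect columns ---------------------------------------------
  class_names <- spec$fixed_class
  nlev <- vapply(records$fixed, nlevels, 0L)
  large <- spec$large_fixed %||%
    (if (length(class_names)) class_names[which.max(nlev)] else NULL)
  f_effect <- character(0); f_level <- character(0)
  col_of <- list()   # per class effect: level -> column (0 = dropped)
  for (e in class_names) {
    levs <- levels(records$fixed[[e]])
    dropped <- if (!identical(e, large) && length(levs) > 1L) 1L else 0L
    cols <- integer(length(levs))
    usable <- if (dropped) levs[-1L] else levs
    cols[match(usable, levs)] <- length(f_effect) + seq_along(usable)
    col_of[[e]] <- cols
    f_effect <- c(f_effect, rep(e, length(usable)))
    f_level <- c(f_level, usable)
  }
  jvec <- if (spec$j_covariates) j_covariates(ped_ops) else NULL
  cov_names <- c(spec$covariates,
                 if (!is.null(jvec)) paste0("J:", spec$channels))
  f_effect <- c(f_effect, rep("covariate", length(cov_names)))
  f_level <- c(f_level, cov_names)
  nf <- length(f_effect)
  f1_cols <- which(f_effect == large)
  f2_cols <- setdiff(seq_len(nf), f1_cols)

  # ---- permanent environment (dam) --------------------------------------
  pe_levels <- if (spec$pe) sort(unique(records$dam[records$dam > 0L]))
               else integer(0)
  npe <- length(pe_levels)
  perank <- integer(ped$n)
  if (npe) perank[pe_levels] <- seq_len(npe)

  # ---- equation offsets --------------------------------------------------
  off_pe <- nf
  off_un <- off_pe + npe * nt
  off_ag <- off_un + n_n * q
  off_g  <- off_ag + n_g * q
  total  <- off_g + n_snp * q
  off_dup <- off_g                      # extended layout replaces g by dup
  ext_total <- off_dup + n_g * q

  # ---- least-squares part: H' R^-1 H over the extended layout ------------
  nrec <- records$n
  rvar <- diag(spec$R0)[records$trait]
  wr <- 1 / sqrt(rvar)
  ti <- list(); tj <- list(); tx <- list(); k <- 0L
  add <- function(rows, cols, vals) {
    k <<- k + 1L; ti[[k]] <<- rows; tj[[k]] <<- cols; tx[[k]] <<- vals
  }
  rows_all <- seq_len(nrec)
  for (e in class_names) {
    cc <- col_of[[e]][as.integer(records$fixed[[e]])]
    keep <- cc > 0L
    add(rows_all[keep], cc[keep], rep(1, sum(keep)))
  }
  if (length(spec$covariates)) {
    base <- length(f_effect) - length(cov_names)
    for (ci in seq_along(spec$covariates))
      add(rows_all, rep(base + ci, nrec), records$covar[, ci])
  }
  # genetic incidences (and J covariates, which share them)
  ncov_user <- length(spec$covariates)
  jcol0 <- nf - length(spec$channels)  # first J column (when fitted)
  gen_hits <- function(type) {
    # type 1 = direct (self), type 2 = maternal (dam)
    anim <- if (type == 1L) records$animal else records$dam
    ok <- anim > 0L
    list(rows = rows_all[ok], anim = anim[ok],
         ch = channel_of(spec, records$trait[ok], type))
  }
  for (type in seq_len(ntypes)) {
    h <- gen_hits(type)
    if (!length(h$rows)) next
    gflag <- ped$genotyped[h$anim]
    # non-genotyped -> u_n columns
    if (any(!gflag)) {
      i0 <- h$rows[!gflag]
      cols <- off_un + (nrank[h$anim[!gflag]] - 1L) * q + h$ch[!gflag]
      add(i0, cols, rep(1, length(i0)))
    }
    if (any(gflag)) {
      i1 <- h$rows[gflag]
      cols_ag <- off_ag + (grank[h$anim[gflag]] - 1L) * q + h$ch[gflag]
      add(i1, cols_ag, rep(1, length(i1)))
      if (variant == "ms") {
        cols_dup <- off_dup + (grank[h$anim[gflag]] - 1L) * q + h$ch[gflag]
        add(i1, cols_dup, rep(1, length(i1)))
      }
    }
    if (!is.null(jvec))  # J covariate of each active channel
      add(h$rows, rep(jcol0, length(h$rows)) + h$ch, jvec[h$anim])
  }
  if (spec$pe) {
    ok <- records$dam > 0L
    cols <- off_pe + (perank[records$dam[ok]] - 1L) * nt + records$trait[ok]
    add(rows_all[ok], cols, rep(1, sum(ok)))
  }
  ncol_H <- if (variant == "ms") ext_total else off_g
  H <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(nrec, ncol_H))
  Hw <- H * wr   # row scaling by 1/sqrt(residual variance)
  C_LS <- as(Matrix::crossprod(Hw), "generalMatrix")
  b_ext <- as.numeric(Matrix::crossprod(Hw, wr * records$y))
  # permanent environment prior precision P0^-1 (x) I folded into C_LS
  if (spec$pe && npe) {
    P0inv <- solve(spec$P0)
    bi <- rep(seq_len(npe), each = nt * nt)
    ii <- off_pe + (bi - 1L) * nt + rep(rep(seq_len(nt), each = nt), npe)
    jj <- off_pe + (bi - 1L) * nt + rep(rep(seq_len(nt), nt), npe)
    C_LS <- C_LS + Matrix::sparseMatrix(i = ii, j = jj,
                                        x = rep(as.vector(P0inv), npe),
                                        dims = dim(C_LS))
  }

  G0inv <- solve(spec$G0)
  m <- cinfo$m
  # right-hand side in the final layout
  b <- numeric(total)
  b[seq_len(off_g)] <- b_ext[seq_len(off_g)]
  if (variant == "ms") {
    bdup <- blk_mat(b_ext[(off_dup + 1L):ext_total], q)
    b[(off_g + 1L):total] <- blk_vec(zt_matmat(geno, cinfo, bdup))
  }  # Liu: SNP block of b is exactly zero

  map <- list(nf = nf, f_effect = f_effect, f_level = f_level,
              f1_cols = f1_cols, f2_cols = f2_cols, large_fixed = large,
              npe = npe, pe_levels = pe_levels, nt = nt, q = q,
              n_n = n_n, n_g = n_g, n_snp = n_snp,
              off_pe = off_pe, off_un = off_un, off_ag = off_ag,
              off_g = off_g, off_dup = off_dup,
              total = total, ext_total = ext_total)
  structure(list(variant = variant, spec = spec, map = map,
                 C_LS = C_LS, b = b, ped_ops = ped_ops, geno = geno,
                 cinfo = cinfo, G0inv = G0inv, m = m, w = spec$w,
                 n_records = nrec),
            class = "ssnpblup_system")
}

#' @export
print.ssnpblup_system <- function(x, ...) {
  cat(sprintf("ssSNPBLUP system (%s): %d equations = %d fixed + %d pe + %d u_n + %d %s + %d SNP\n",
              toupper(x$variant), x$map$total, x$map$nf, x$map$npe * x$map$nt,
              x$map$n_n * x$map$q,
              x$map$n_g * x$map$q, if (x$variant == "ms") "a_g" else "u_g",
              x$map$n_snp * x$map$q))
  invisible(x)
}

split_x <- function(sys, x) {
  m <- sys$map
  list(f = x[seq_len(m$off_un)],     # fixed + permanent environment
       un = blk_mat(x[(m$off_un + 1L):m$off_ag], m$q),
       ag = blk_mat(x[(m$off_ag + 1L):m$off_g], m$q),
       g  = blk_mat(x[(m$off_g + 1L):m$total], m$q))
}

#' Apply the coefficient matrix of an assembled system to a vector
#'
#' Matrix-free product following the split form: the SNP block of `x` is
#' mapped through Z, the sparse least-squares part and the pedigree parts
#' are applied, and the duplicate genotyped channel is mapped back
#' through Z'. The two Q products of the Mantysaari-Stranden route (and
#' the two \eqn{A_{gg}^{-1}} products of the Liu route) are computed once
#' on batched columns and reused.
#'
#' @param sys An [assemble_system()] result.
#' @param x Numeric vector, `sys$map$total` long.
#' @return Numeric vector `C %*% x`.
#' @export
system_matvec <- function(sys, x) {
  m <- sys$map
  if (length(x) != m$total) stop("matvec: dimension mismatch")
  p <- split_x(sys, x)
  Gi <- sys$G0inv; w <- sys$w
  ops <- sys$ped_ops
  zg <- z_matmat(sys$geno, sys$cinfo, p$g)          # n_g x q
  if (sys$variant == "ms") {
    v1 <- c(p$f, blk_vec(p$un), blk_vec(p$ag), blk_vec(zg))
    y1 <- as.numeric(sys$C_LS %*% v1)
    yf <- y1[seq_len(m$off_un)]
    yun <- blk_mat(y1[(m$off_un + 1L):m$off_ag], m$q)
    yag <- blk_mat(y1[(m$off_ag + 1L):m$off_g], m$q)
    ydup <- blk_mat(y1[(m$off_dup + 1L):m$ext_total], m$q)
    qa <- q_matmat(ops, p$ag); qz <- q_matmat(ops, zg)  # the only two Q products
    if (m$n_n) yun <- yun + as.matrix(ops$Ang %*% zg) %*% Gi
    yag <- yag + ((1 - 1 / w) * qa + qz) %*% Gi
    ydup <- ydup + ((if (m$n_n) as.matrix(ops$Agn %*% p$un) else 0) +
                      qa + qz) %*% Gi
    yg <- zt_matmat(sys$geno, sys$cinfo, ydup)
    # C_R2
    if (m$n_n) {
      yun <- yun + (as.matrix(ops$Ann %*% p$un) +
                      as.matrix(ops$Ang %*% p$ag)) %*% Gi
      yag <- yag + as.matrix(ops$Agn %*% p$un) %*% Gi
    }
    yag <- yag + (1 / w) * as.matrix(ops$Agg %*% p$ag) %*% Gi
    yg <- yg + (sys$m / (1 - w)) * p$g %*% Gi
  } else {
    v <- c(p$f, blk_vec(p$un), blk_vec(p$ag))   # ag slot holds u_g for Liu
    y1 <- as.numeric(sys$C_LS %*% v)
    yf <- y1[seq_len(m$off_un)]
    yun <- blk_mat(y1[(m$off_un + 1L):m$off_ag], m$q)
    yag <- blk_mat(y1[(m$off_ag + 1L):m$off_g], m$q)
    p1 <- agg_inv_matmat(ops, p$ag)             # the only two A_gg^-1 products
    p2 <- agg_inv_matmat(ops, zg)
    yag <- yag + ((1 / w - 1) * p1 - (1 / w) * p2) %*% Gi
    ydup <- ((1 / w) * (p2 - p1)) %*% Gi
    yg <- zt_matmat(sys$geno, sys$cinfo, ydup)
    if (m$n_n) {
      yun <- yun + (as.matrix(ops$Ann %*% p$un) +
                      as.matrix(ops$Ang %*% p$ag)) %*% Gi
      yag <- yag + as.matrix(ops$Agn %*% p$un) %*% Gi
    }
    yag <- yag + as.matrix(ops$Agg %*% p$ag) %*% Gi
    yg <- yg + (sys$m / (1 - w)) * p$g %*% Gi
  }
  c(yf, blk_vec(yun), blk_vec(yag), blk_vec(yg))
}

#' Tidy solution table for a solved system
#'
#' @param sys An [assemble_system()] result.
#' @param x Solution vector.
#' @return Data frame with one row per equation: block, effect/level
#'   labels, channel, estimate.
#' @export
solution_table <- function(sys, x) {
  m <- sys$map; ped <- sys$ped_ops$ped
  chan <- sys$spec$channels
  out <- list()
  out$fixed <- data.frame(block = "fixed", effect = m$f_effect,
                          level = m$f_level, channel = NA_character_,
                          estimate = x[seq_len(m$nf)])
  if (m$npe)
    out$pe <- data.frame(block = "pe", effect = "pe",
                         level = rep(ped$original_id[m$pe_levels],
                                     each = m$nt),
                         channel = rep(sys$spec$traits, m$npe),
                         estimate = x[(m$off_pe + 1L):m$off_un])
  lab <- function(idx) rep(ped$original_id[idx], each = m$q)
  if (m$n_n)
    out$un <- data.frame(block = "u_n", effect = "genetic",
                         level = lab(sys$ped_ops$n_index),
                         channel = rep(chan, m$n_n),
                         estimate = x[(m$off_un + 1L):m$off_ag])
  out$ag <- data.frame(block = if (sys$variant == "ms") "a_g" else "u_g",
                       effect = "genetic",
                       level = lab(sys$ped_ops$g_index),
                       channel = rep(chan, m$n_g),
                       estimate = x[(m$off_ag + 1L):m$off_g])
  out$g <- data.frame(block = "snp", effect = "snp",
                      level = rep(sys$geno$snp_ids, each = m$q),
                      channel = rep(chan, m$n_snp),
                      estimate = x[(m$off_g + 1L):m$total])
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Total additive genetic effects of genotyped animals
#'
#' For the Mantysaari-Stranden parameterisation this is
#' `u_g = a_g + Z g`; for the Liu parameterisation `u_g` is a solution
#' block itself.
#'
#' @param sys An [assemble_system()] result.
#' @param x Solution vector.
#' @return `n_g x q` matrix.
#' @export
genotyped_breeding_values <- function(sys, x) {
  p <- split_x(sys, x)
  if (sys$variant == "ms") p$ag + z_matmat(sys$geno, sys$cinfo, p$g)
  else p$ag
}

#' Compare the solutions of the two equivalent parameterisations
#'
#' The MS and Liu systems are reparameterisations of the same model: after
#' exact solution, fixed effects, `u_n`, SNP effects and the total
#' genotyped breeding values `u_g` (for MS, `a_g + Z g`) must agree.
#'
#' @param sys_ms,sys_liu Assembled systems on identical inputs.
#' @param x_ms,x_liu Their solution vectors.
#' @param rel_resid_ms,rel_resid_liu Final relative residual norms of the
#'   two solves; if either exceeds `resid_tol` the report is flagged
#'   non-comparable.
#' @param resid_tol Residual threshold for comparability.
#' @return List of class `ssnpblup_equivalence`: maximum absolute
#'   differences and correlations per block, plus a `comparable` flag.
#' @export
solutions_equivalent <- function(sys_ms, x_ms, sys_liu, x_liu,
                                 rel_resid_ms = 0, rel_resid_liu = 0,
                                 resid_tol = 1e-6) {
  stopifnot(sys_ms$variant == "ms", sys_liu$variant == "liu")
  comparable <- is.finite(rel_resid_ms) && is.finite(rel_resid_liu) &&
    rel_resid_ms <= resid_tol && rel_resid_liu <= resid_tol
  ug_ms <- genotyped_breeding_values(sys_ms, x_ms)
  ug_liu <- genotyped_breeding_values(sys_liu, x_liu)
  m <- sys_ms$map
  block <- function(x, from, to) x[(from + 1L):to]
  d <- function(a, b) max(abs(a - b), 0)
  structure(list(
    comparable = comparable,
    max_abs_ug_diff = d(ug_ms, ug_liu),
    cor_ug = if (length(ug_ms) > 1) stats::cor(as.vector(ug_ms),
                                               as.vector(ug_liu)) else NA,
    max_abs_fixed_diff = d(x_ms[seq_len(m$off_un)],
                           x_liu[seq_len(m$off_un)]),
    max_abs_un_diff = if (m$n_n) d(block(x_ms, m$off_un, m$off_ag),
                                   block(x_liu, m$off_un, m$off_ag)) else 0,
    max_abs_g_diff = d(block(x_ms, m$off_g, m$total),
                       block(x_liu, m$off_g, m$total)),
    rel_resid_ms = rel_resid_ms, rel_resid_liu = rel_resid_liu),
    class = "ssnpblup_equivalence")
}

#' @export
print.ssnpblup_equivalence <- function(x, ...) {
  if (!x$comparable)
    cat("WARNING: inputs not solved to tolerance; differences are not meaningful\n")
  cat(sprintf("MS vs Liu solutions: max|u_g diff| = %.3g (cor %.6f), max|fixed diff| = %.3g, max|g diff| = %.3g\n",
              x$max_abs_ug_diff, x$cor_ug, x$max_abs_fixed_diff,
              x$max_abs_g_diff))
  invisible(x)
}
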