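#' Approximated block-diagonal preconditioner
#'
#' Builds the preconditioner `M` for either single-step system:
#' a purely diagonal part for the designated large fixed effect (f1), a
#' sparse, ridge-regularised and factorized part for the remaining fixed
#' columns (f2, ridge `1e-4 * diag`), and one small symmetric block per
#' random-effect level (traits/channels within a level). The genotyped
#' animal blocks use the Monte-Carlo estimate of \eqn{diag(A_{gg}^{-1})}
#' (both parameterisations share the formula
#' \eqn{\Sigma^{22} = A^{gg} + (1/w - 1) A_{gg}^{-1}}); the SNP-block
#' diagonal uses the per-SNP closed forms
#' \eqn{diag(Z' A_{gg}^{-1} Z)_j \approx 2 n_g p_j (1 - p_j)} (Liu) and
#' \eqn{diag(Z' Q Z)_j \approx (2 n_g + n_{offspring}) p_j (1 - p_j)}
#' (MS), plus the exact prior term `m/(1-w)` and, for MS, the exactly
#' computed data part \eqn{diag(Z' W_g' R_g^{-1} W_g Z)} obtained by a
#' blocked pass over the packed genotypes.
#'
#' @param sys An [assemble_system()] result.
#' @param mc_samples Monte-Carlo probes for `diag(A_gg^-1)` (default 1000).
#' @param seed Seed for the Monte-Carlo estimator.
#' @param exact Replace the approximated terms (Monte-Carlo and per-SNP
#'   closed forms) by exact diagonals computed densely; small systems
#'   only. Used to verify that the approximations do not change the
#'   convergence behaviour.
#' @param block_snps SNP panel width of the blocked exact pass.
#' @return An object of class `ssnpblup_preconditioner`.
#' @export
build_preconditioner <- function(sys, mc_samples = 1000, seed = 1,
                                 exact = FALSE, block_snps = 64L) {
  m <- sys$map; q <- m$q; nt <- m$nt
  ops <- sys$ped_ops; Gi <- sys$G0inv; w <- sys$w
  d_all <- Matrix::diag(sys$C_LS)

  # ---- fixed part --------------------------------------------------------
  d_f1 <- d_all[m$f1_cols]
  if (length(d_f1) && any(d_f1 <= 0))
    stop("non-positive diagonal in block f1 (", m$large_fixed, ")")
  chol_f2 <- NULL; C_f2 <- NULL
  if (length(m$f2_cols)) {
    C_f2 <- sys$C_LS[m$f2_cols, m$f2_cols, drop = FALSE] +
      Matrix::Diagonal(length(m$f2_cols), 1e-4 * d_all[m$f2_cols])
    chol_f2 <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(C_f2), LDL = FALSE,
                       perm = TRUE),
      error = function(e) stop("block f2 is not positive definite: ",
                               conditionMessage(e)))
  }

  # data-part diagonal blocks of C_LS for a level range, channel-fastest
  trip <- Matrix::summary(sys$C_LS)
  level_blocks <- function(off, n_level, nch) {
    arr <- array(0, dim = c(n_level, nch, nch))
    if (!n_level) return(arr)
    lo <- off + 1L; hi <- off + n_level * nch
    sel <- trip$i >= lo & trip$i <= hi & trip$j >= lo & trip$j <= hi
    ii <- trip$i[sel] - off; jj <- trip$j[sel] - off
    li <- (ii - 1L) %/% nch + 1L; lj <- (jj - 1L) %/% nch + 1L
    same <- li == lj
    ci <- ii[same] - (li[same] - 1L) * nch
    cj <- jj[same] - (lj[same] - 1L) * nch
    arr[cbind(li[same], ci, cj)] <- trip$x[sel][same]
    arr
  }

  add_outer <- function(arr, scal, B) {
    # arr[l,,] += scal[l] * B for all levels
    for (a in seq_len(dim(arr)[2])) for (b in seq_len(dim(arr)[3]))
      arr[, a, b] <- arr[, a, b] + scal * B[a, b]
    arr
  }

  # ---- permanent environment (prior already folded into C_LS) -----------
  pe_blocks <- level_blocks(m$off_pe, m$npe, nt)

  # ---- non-genotyped animals: exact diagonal -----------------------------
  un_blocks <- level_blocks(m$off_un, m$n_n, q)
  if (m$n_n) {
    dAnn <- Matrix::diag(ops$Ann)
    un_blocks <- add_outer(un_blocks, dAnn, Gi)
  }

  # ---- genotyped animals: Sigma22 = A^gg + (1/w - 1) A_gg^-1 -------------
  ag_blocks <- level_blocks(m$off_ag, m$n_g, q)
  d_agg_inv <- if (exact)
    diag(agg_inv_matmat(ops, diag(m$n_g))) else
    mc_diag_agg_inverse(ops, n_samples = mc_samples, seed = seed)
  ag_blocks <- add_outer(ag_blocks,
                         Matrix::diag(ops$Agg) + (1 / w - 1) * d_agg_inv, Gi)

  # ---- SNP equations -----------------------------------------------------
  p <- sys$cinfo$p
  snp_scal <- if (sys$variant == "liu") {
    dz <- if (exact) exact_diag_zaz(sys, "agg_inv", block_snps) else
      snp_diag_approximation(m$n_g, p, variant = "liu")
    (1 / w) * dz + sys$m / (1 - w)
  } else {
    dz <- if (exact) exact_diag_zaz(sys, "q", block_snps) else
      snp_diag_approximation(m$n_g, p,
                             n_offspring = count_genotyped_parent_links(ops$ped),
                             variant = "ms")
    dz + sys$m / (1 - w)
  }
  snp_blocks <- add_outer(array(0, dim = c(m$n_snp, q, q)), snp_scal, Gi)
  if (sys$variant == "ms")
    snp_blocks <- snp_blocks + ms_snp_data_diag(sys, block_snps)

  inv_blocks <- function(arr, label) {
    n <- dim(arr)[1L]
    if (!n) return(arr)
    inv <- arr
    for (l in seq_len(n)) {
      bl <- matrix(arr[l, , ], dim(arr)[2L])
      bl <- (bl + t(bl)) / 2
      ev <- tryCatch(chol(bl), error = function(e) NULL)
      if (is.null(ev))
        stop("preconditioner block not positive definite: ", label,
             " level ", l)
      inv[l, , ] <- chol2inv(ev)
    }
    inv
  }
  structure(list(
    map = m, variant = sys$variant,
    d_f1 = d_f1, C_f2 = C_f2, chol_f2 = chol_f2,
    pe_blocks = pe_blocks, un_blocks = un_blocks, ag_blocks = ag_blocks,
    snp_blocks = snp_blocks,
    pe_inv = inv_blocks(pe_blocks, "pe"),
    un_inv = inv_blocks(un_blocks, "u_n"),
    ag_inv = inv_blocks(ag_blocks, "genotyped"),
    snp_inv = inv_blocks(snp_blocks, "snp"),
    d_agg_inv = d_agg_inv),
    class = "ssnpblup_preconditioner")
}

#' Closed-form per-SNP diagonal approximations for the preconditioner
#'
#' The j-th diagonal element of \eqn{Z' A_{gg}^{-1} Z} is approximated by
#' `2 * n_g * p_j * (1 - p_j)` (Liu system) and the j-th diagonal element
#' of \eqn{Z' Q Z} by `(2 * n_g + n_offspring) * p_j * (1 - p_j)` (MS
#' system), where `n_offspring` is the total number of offspring of the
#' genotyped animals.
#'
#' @param n_g Number of genotyped animals.
#' @param p Observed allele frequencies (vector).
#' @param n_offspring Offspring-link count (MS only; see
#'   [count_genotyped_parent_links()]).
#' @param variant `"liu"` or `"ms"`.
#' @return Numeric vector, one approximated diagonal term per SNP.
#' @export
snp_diag_approximation <- function(n_g, p, n_offspring = 0,
                                   variant = c("liu", "ms")) {
  variant <- match.arg(variant)
  pq <- p * (1 - p)
  if (variant == "liu") 2 * n_g * pq else (2 * n_g + n_offspring) * pq
}

# exact diag(Z' A_gg^-1 Z) or diag(Z' Q Z) by a blocked pass (small systems)
exact_diag_zaz <- function(sys, kind = c("agg_inv", "q"), block_snps = 64L) {
  kind <- match.arg(kind)
  pg <- sys$geno; ci <- sys$cinfo
  out <- numeric(pg$n_snp)
  j0 <- 1L
  while (j0 <= pg$n_snp) {
    j1 <- min(j0 + block_snps - 1L, pg$n_snp)
    Zb <- plink_decode_centered_cpp(pg$codes, pg$n_g, pg$n_snp, ci$p, j0, j1)
    az <- if (kind == "agg_inv") agg_inv_matmat(sys$ped_ops, Zb)
          else q_matmat(sys$ped_ops, Zb)
    out[j0:j1] <- colSums(Zb * az)
    j0 <- j1 + 1L
  }
  out
}

# exact per-SNP q x q data blocks diag(Z' W_g' R_g^-1 W_g Z) for the MS
# system, from the duplicate-channel block of C_LS and a blocked decode
ms_snp_data_diag <- function(sys, block_snps = 64L) {
  m <- sys$map; q <- m$q
  pg <- sys$geno; ci <- sys$cinfo
  E <- sys$C_LS[(m$off_dup + 1L):m$ext_total,
                (m$off_dup + 1L):m$ext_total, drop = FALSE]
  out <- array(0, dim = c(m$n_snp, q, q))
  idx <- function(ch) seq(ch, m$n_g * q, by = q)
  for (a in seq_len(q)) for (b in a:q) {
    Eab <- E[idx(a), idx(b), drop = FALSE]
    if (length(Eab@x) == 0) next
    j0 <- 1L
    while (j0 <= m$n_snp) {
      j1 <- min(j0 + block_snps - 1L, m$n_snp)
      Zb <- plink_decode_centered_cpp(pg$codes, pg$n_g, pg$n_snp, ci$p,
                                      j0, j1)
      v <- colSums(Zb * as.matrix(Eab %*% Zb))
      out[j0:j1, a, b] <- out[j0:j1, a, b] + v
      if (a != b) out[j0:j1, b, a] <- out[j0:j1, b, a] + v
      j0 <- j1 + 1L
    }
  }
  out
}

# y[l, ] = arr[l, , ] %*% r[l, ] for all levels, vectorised over levels
apply_blocks <- function(arr, rmat) {
  nch <- dim(arr)[2L]
  out <- matrix(0, nrow(rmat), nch)
  for (a in seq_len(nch)) for (b in seq_len(nch))
    out[, a] <- out[, a] + arr[, a, b] * rmat[, b]
  out
}

precond_apply <- function(M, r, inverse = TRUE) {
  m <- M$map
  out <- numeric(m$total)
  if (length(M$d_f1))
    out[m$f1_cols] <- if (inverse) r[m$f1_cols] / M$d_f1
                      else r[m$f1_cols] * M$d_f1
  if (length(m$f2_cols))
    out[m$f2_cols] <- if (inverse)
      as.numeric(Matrix::solve(M$chol_f2, r[m$f2_cols], system = "A"))
    else as.numeric(M$C_f2 %*% r[m$f2_cols])
  seg <- function(off, n, nch, arr) {
    if (!n) return()
    idx <- (off + 1L):(off + n * nch)
    out[idx] <<- blk_vec(apply_blocks(arr, blk_mat(r[idx], nch)))
  }
  seg(m$off_pe, m$npe, m$nt, if (inverse) M$pe_inv else M$pe_blocks)
  seg(m$off_un, m$n_n, m$q, if (inverse) M$un_inv else M$un_blocks)
  seg(m$off_ag, m$n_g, m$q, if (inverse) M$ag_inv else M$ag_blocks)
  seg(m$off_g, m$n_snp, m$q, if (inverse) M$snp_inv else M$snp_blocks)
  out
}

#' Second-level diagonal preconditioner D
#'
#' Diagonal scaling applied after `M^{-1}`: the entries of all SNP-effect
#' equations (direct and maternal channels alike) equal `d_snp`, all
#' other entries equal 1. Defaults to `1e3` for the Mantysaari-Stranden
#' system and `1e2` for the Liu system. `d_snp` is constant over the
#' whole SNP block, so `D^{-1} M^{-1}` remains symmetric.
#'
#' @param sys An [assemble_system()] result.
#' @param d_snp Override for the SNP-equation value.
#' @return List of class `ssnpblup_second_level` with the diagonal in `$d`.
#' @export
second_level_d <- function(sys, d_snp = NULL) {
  d_snp <- d_snp %||% if (sys$variant == "ms") 1e3 else 1e2
  stopifnot(d_snp > 0)
  m <- sys$map
  d <- rep(1, m$total)
  if (m$n_snp) d[(m$off_g + 1L):m$total] <- d_snp
  structure(list(d = d, d_snp = d_snp), class = "ssnpblup_second_level")
}

#' Apply the two-level preconditioner to a residual
#'
#' Returns `D^{-1} M^{-1} r`: block-wise solves for the random-effect
#' blocks and the f2 factorization, element-wise division for the f1
#' diagonal, then element-wise division by `D`.
#'
#' @param M [build_preconditioner()] output.
#' @param D [second_level_d()] output (or `NULL` for `D = I`).
#' @param r Residual vector.
#' @return Numeric vector.
#' @export
apply_two_level <- function(M, D, r) {
  if (length(r) != M$map$total) stop("preconditioner layout mismatch")
  z <- precond_apply(M, r, inverse = TRUE)
  if (!is.null(D)) z <- z / D$d
  z
}

#' Preconditioned conjugate gradients with a two-level preconditioner
#'
#' Standard PCG on `C x = b` started from `x = 0`, with preconditioner
#' application `z = D^{-1} M^{-1} r`. Convergence is declared when the
#' recursively updated residual satisfies `||r_k|| / ||b|| < tol` (2-norm);
#' the residual is refreshed from a true computation `b - C x` every
#' `audit_every` iterations and once more at termination, which guards
#' against recursion drift. The alpha/beta coefficient series are kept
#' for the Lanczos eigenvalue estimates.
#'
#' @param sys An [assemble_system()] result, a function `f(x)` applying
#'   the operator, or a matrix.
#' @param M,D Preconditioner parts (`NULL` = identity).
#' @param b Right-hand side; defaults to the assembled system's.
#' @param tol Relative residual tolerance (default `1e-6`).
#' @param max_iter Iteration cap.
#' @param audit_every True-residual refresh period.
#' @param lanczos Estimate extreme eigenvalues at exit.
#' @return An object of class `ssnpblup_solve_report`: `solution`,
#'   `n_iter`, `rel_residuals`, `alphas`, `betas`, `converged`,
#'   `true_rel_residual`, and (when estimable) `eig_min`, `eig_max`,
#'   `cond`.
#' @export
pcg_solve <- function(sys, M = NULL, D = NULL, b = NULL, tol = 1e-6,
                      max_iter = 5000L, audit_every = 100L,
                      lanczos = TRUE) {
  apply_C <- if (inherits(sys, "ssnpblup_system")) {
    if (is.null(b)) b <- sys$b
    function(x) system_matvec(sys, x)
  } else if (is.function(sys)) sys
  else { mat <- sys; function(x) as.numeric(mat %*% x) }
  if (is.null(b)) stop("b is required when sys is not an assembled system")
  n <- length(b)
  P <- if (is.null(M) && is.null(D)) identity
       else if (is.null(M)) function(r) r / D$d
       else function(r) apply_two_level(M, D, r)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(structure(list(solution = numeric(n), n_iter = 0L,
                          rel_residuals = numeric(0), alphas = numeric(0),
                          betas = numeric(0), converged = TRUE,
                          true_rel_residual = 0, eig_min = NA, eig_max = NA,
                          cond = NA), class = "ssnpblup_solve_report"))
  x <- numeric(n)
  r <- b
  z <- P(r)
  p <- z
  rz <- sum(r * z)
  alphas <- numeric(0); betas <- numeric(0); rel <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    Cp <- apply_C(p)
    pCp <- sum(p * Cp)
    if (!is.finite(pCp) || pCp <= 0)
      stop(sprintf("indefinite preconditioned operator detected at iteration %d (p'Cp = %g)",
                   k, pCp))
    alpha <- rz / pCp
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (k %% audit_every == 0L) r <- b - apply_C(x)
    relres <- sqrt(sum(r^2)) / bnorm
    alphas <- c(alphas, alpha); rel <- c(rel, relres)
    if (relres < tol) { converged <- TRUE; break }
    z <- P(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    betas <- c(betas, beta)
    rz <- rz_new
    p <- z + beta * p
  }
  true_rel <- sqrt(sum((b - apply_C(x))^2)) / bnorm
  rep <- structure(list(solution = x, n_iter = length(alphas),
                        rel_residuals = rel, alphas = alphas, betas = betas,
                        converged = converged, true_rel_residual = true_rel,
                        eig_min = NA_real_, eig_max = NA_real_,
                        cond = NA_real_),
                   class = "ssnpblup_solve_report")
  if (lanczos && rep$n_iter >= 2L) {
    ext <- lanczos_extremes(rep)
    rep$eig_min <- ext$eig_min; rep$eig_max <- ext$eig_max
    rep$cond <- ext$cond
  }
  rep
}

#' Extreme eigenvalues of the preconditioned operator from PCG coefficients
#'
#' Builds the Lanczos tridiagonal matrix associated with the conjugate
#' gradient run: diagonal `1/alpha_k + beta_{k-1}/alpha_{k-1}` (with
#' `beta_0 = 0`), off-diagonal `sqrt(beta_k)/alpha_k`. Its extreme
#' eigenvalues estimate the extreme eigenvalues of `D^{-1} M^{-1} C`, and
#' their ratio is the effective spectral condition number, the quantity
#' that governs PCG convergence.
#'
#' @param report A [pcg_solve()] report with at least 2 iterations.
#' @return List `eig_min`, `eig_max`, `cond`.
#' @export
lanczos_extremes <- function(report) {
  k <- length(report$alphas)
  if (k < 2L) stop("Lanczos estimates need at least 2 recorded iterations")
  a <- report$alphas; b <- report$betas[seq_len(k - 1L)]
  d <- 1 / a + c(0, b / a[-k])
  e <- sqrt(pmax(b, 0)) / a[-k]
  Tm <- diag(d)
  for (i in seq_len(k - 1L)) {
    Tm[i, i + 1L] <- e[i]; Tm[i + 1L, i] <- e[i]
  }
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  list(eig_min = min(ev), eig_max = max(ev), cond = max(ev) / min(ev))
}

#' @export
print.ssnpblup_solve_report <- function(x, ...) {
  cat(sprintf("PCG solve: %d iterations, %s (rel. residual %.3g, true %.3g)\n",
              x$n_iter, if (x$converged) "converged" else "NOT converged",
              if (length(x$rel_residuals)) x$rel_residuals[x$n_iter] else NA,
              x$true_rel_residual))
  if (is.finite(x$cond))
    cat(sprintf("  Lanczos estimates: eig_min %.4g, eig_max %.4g, effective condition number %.4g\n",
                x$eig_min, x$eig_max, x$cond))
  invisible(x)
}
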