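test_that("PCG basics: identity system, SPD system vs dense solve, failure modes", {
  # C = I, M = I: one iteration, x = b
  r <- pcg_solve(diag(5), b = 1:5, tol = 1e-10)
  expect_true(r$converged)
  expect_equal(r$n_iter, 1L)
  expect_equal(r$solution, as.numeric(1:5))
  # zero right-hand side short-circuits
  r0 <- pcg_solve(diag(3), b = numeric(3))
  expect_true(r0$converged)
  expect_equal(r0$n_iter, 0L)
  # random SPD system vs dense solve
  set.seed(4)
  B <- matrix(rnorm(50 * 50), 50)
  C <- crossprod(B) + diag(50)
  b <- rnorm(50)
  rs <- pcg_solve(C, b = b, tol = 1e-10, max_iter = 500)
  expect_true(rs$converged)
  expect_lt(max(abs(rs$solution - solve(C, b))) / max(abs(solve(C, b))),
            1e-5)
  # iteration cap: partial report, converged = FALSE
  rcap <- pcg_solve(C, b = b, tol = 1e-14, max_iter = 3)
  expect_false(rcap$converged)
  expect_equal(rcap$n_iter, 3L)
  expect_length(rcap$rel_residuals, 3L)
  # indefinite operator detected
  expect_error(pcg_solve(diag(c(1, -1)), b = c(1, 1)), "indefinite")
})

test_that("PCG residual trajectory: M-norm error decreases monotonically", {
  set.seed(9)
  B <- matrix(rnorm(30 * 30), 30)
  C <- crossprod(B) + diag(30)
  b <- rnorm(30)
  xstar <- solve(C, b)
  # track errors by re-running with growing iteration caps
  errs <- vapply(1:12, function(k) {
    xk <- pcg_solve(C, b = b, tol = 0, max_iter = k)$solution
    sqrt(sum((xk - xstar) * (C %*% (xk - xstar))))   # C-norm = M-norm, M = I
  }, 0)
  expect_true(all(diff(errs) < 1e-8))
})

test_that("two-level preconditioner application is exact per block", {
  ds <- tiny_bivariate()
  sys <- assemble_system(ds$spec, ds$rs, ds$ops, ds$pg, variant = "liu")
  M <- build_preconditioner(sys, mc_samples = 500, seed = 2)
  D <- second_level_d(sys)
  expect_equal(D$d_snp, 1e2)
  expect_equal(second_level_d(assemble_system(ds$spec, ds$rs, ds$ops, ds$pg,
                                              variant = "ms"))$d_snp, 1e3)
  set.seed(11)
  for (k in 1:20) {
    r <- rnorm(sys$map$total)
    # M then M^-1 round-trips (D = NULL)
    mr <- ssnpblup:::precond_apply(M, r, inverse = FALSE)
    back <- apply_two_level(M, NULL, mr)
    expect_lt(max(abs(back - r)), 1e-10 * max(1, max(abs(r))))
    # with D: apply_two_level is elementwise D^-1 after M^-1
    expect_equal(apply_two_level(M, D, mr), back / D$d)
  }
  # r = M e_k maps back to e_k
  e <- numeric(sys$map$total); e[sys$map$off_g + 3L] <- 1
  expect_lt(max(abs(apply_two_level(M, NULL,
                                    ssnpblup:::precond_apply(M, e, FALSE)) - e)),
            1e-12)
  expect_error(apply_two_level(M, D, numeric(3)), "layout mismatch")
})

test_that("Lanczos estimates recover closed-form extreme eigenvalues", {
  # diag(1, 10), run to termination: estimates {1, 10}, cond 10
  r <- pcg_solve(diag(c(1, 10)), b = c(1, 1), tol = 1e-12, max_iter = 10)
  ext <- lanczos_extremes(r)
  expect_equal(ext$eig_min, 1, tolerance = 1e-8)
  expect_equal(ext$eig_max, 10, tolerance = 1e-8)
  expect_equal(ext$cond, 10, tolerance = 1e-8)
  # exactly preconditioned system: a single iteration, estimates undefined
  r1 <- pcg_solve(diag(4), b = rep(1, 4))
  expect_equal(r1$n_iter, 1L)
  expect_error(lanczos_extremes(r1), "at least 2")
  expect_true(is.na(r1$cond))
  # eig_max non-decreasing, eig_min non-increasing over iterations
  set.seed(13)
  B <- matrix(rnorm(40 * 40), 40)
  C <- crossprod(B) + diag(40)
  full <- pcg_solve(C, b = rnorm(40), tol = 1e-13, max_iter = 60)
  track <- t(vapply(2:full$n_iter, function(k) {
    sub <- list(alphas = full$alphas[1:k], betas = full$betas[1:(k - 1)])
    unlist(lanczos_extremes(sub)[c("eig_min", "eig_max")])
  }, c(eig_min = 0, eig_max = 0)))
  expect_true(all(diff(track[, "eig_max"]) > -1e-8))
  expect_true(all(diff(track[, "eig_min"]) < 1e-8))
})

test_that("Lanczos matches a dense eigensolver on a preconditioned system", {
  ds <- tiny_dataset("lanczos", n_founders = 14L, n_generations = 2L,
                     offspring_per_mating = 2L, n_snp = 12L,
                     genotyping_rate = c(0, 0.5, 0.7),
                     fixed_levels = c(hys = 3L), fixed_sd = c(hys = 1),
                     traits = "t1", missing_rate = 0, seed = 71L)
  spec <- model_spec(traits = "t1", fixed_class = "hys", G0 = 1, R0 = 2,
                     w = 0.05)
  rs <- record_set(ds$records, spec, ds$ped)
  sys <- assemble_system(spec, rs, ds$ops, ds$pg, variant = "liu")
  M <- build_preconditioner(sys, mc_samples = 2000, seed = 3)
  D <- second_level_d(sys)
  # run to tight tolerance (past the nominal dimension: finite-precision
  # PCG on an ill-conditioned operator needs more than n iterations)
  r <- pcg_solve(sys, M, D, tol = 1e-13, max_iter = 5L * sys$map$total)
  Cd <- dense_from_matvec(sys)
  P <- diag(1 / D$d) %*%
    t(vapply(seq_len(sys$map$total), function(i) {
      e <- numeric(sys$map$total); e[i] <- 1
      ssnpblup:::precond_apply(M, e, inverse = TRUE)
    }, numeric(sys$map$total)))
  ev <- eigen(P %*% Cd, only.values = TRUE)$values
  ev <- sort(Re(ev))
  expect_lt(abs(r$eig_max - max(ev)) / max(ev), 0.01)
  expect_lt(abs(r$eig_min - min(ev)) / min(ev), 0.01)
})

test_that("maternal simulation: simulate -> assemble -> PCG matches dense solves", {
  ds <- tiny_bivariate()
  for (v in c("ms", "liu")) {
    sys <- assemble_system(ds$spec, ds$rs, ds$ops, ds$pg, variant = v)
    M <- build_preconditioner(sys, mc_samples = 500, seed = 2)
    D <- second_level_d(sys)
    r <- pcg_solve(sys, M, D, tol = 1e-9, max_iter = 2000)
    expect_true(r$converged)
    xd <- solve(dense_from_matvec(sys), sys$b)
    expect_lt(max(abs(r$solution - xd)) / max(abs(xd)), 1e-5)
    expect_true(is.finite(r$cond) && r$cond > 1)
  }
})

test_that("SNP-block diagonal approximations evaluate the printed formulas", {
  # n_g = 200, p = 0.25, no offspring: both terms equal 75
  expect_equal(snp_diag_approximation(200, 0.25, variant = "liu"), 75)
  expect_equal(snp_diag_approximation(200, 0.25, n_offspring = 0,
                                      variant = "ms"), 75)
  # offspring links raise the MS term only
  expect_equal(snp_diag_approximation(200, 0.25, n_offspring = 40,
                                      variant = "ms"),
               (400 + 40) * 0.25 * 0.75)
})

test_that("univariate preconditioner blocks equal exact scalar diagonals", {
  ds <- tiny_dataset("uni_prec", n_founders = 16L, n_generations = 2L,
                     offspring_per_mating = 2L, n_snp = 10L,
                     genotyping_rate = c(0, 0.4, 0.6),
                     fixed_levels = c(hys = 3L), fixed_sd = c(hys = 1),
                     traits = "t1", missing_rate = 0, seed = 55L)
  spec <- model_spec(traits = "t1", fixed_class = "hys", G0 = 1.5, R0 = 2,
                     w = 0.05)
  rs <- record_set(ds$records, spec, ds$ped)
  sys <- assemble_system(spec, rs, ds$ops, ds$pg, variant = "liu")
  M <- build_preconditioner(sys, exact = TRUE)
  Cd <- dense_from_matvec(sys)
  m <- sys$map
  # u_n blocks are 1x1 and equal the exact diagonal of C
  expect_equal(as.numeric(M$un_blocks),
               diag(Cd)[(m$off_un + 1L):m$off_ag])
  # with exact = TRUE the genotyped and SNP blocks are exact too
  expect_equal(as.numeric(M$ag_blocks),
               diag(Cd)[(m$off_ag + 1L):m$off_g], tolerance = 1e-10)
  expect_equal(as.numeric(M$snp_blocks),
               diag(Cd)[(m$off_g + 1L):m$total], tolerance = 1e-10)
})
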