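# univariate micro-system: trio pedigree, 2 genotyped, 2 SNPs, 4 records
uni_fixture <- function(w = 0.05) {
  ped <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                  genotyped = c(TRUE, FALSE, TRUE))
  dos <- matrix(c(0L, 2L, 1L, 1L), 2, 2)   # animals {1, 3} x 2 SNPs
  pg <- pack_genotypes(dos, animal_ids = ped$original_id[c(1, 3)])
  spec <- model_spec(traits = "t1", fixed_class = "herd", G0 = 1.2,
                     R0 = 2.0, w = w)
  df <- data.frame(trait = "t1", y = c(1.0, -0.5, 2.0, 0.3),
                   animal = c(1L, 2L, 3L, 3L), herd = c(1L, 2L, 1L, 2L))
  rs <- record_set(df, spec, ped)
  ops <- extract_ancestor_blocks(ped, account_inbreeding = TRUE)
  list(ped = ped, pg = pg, dos = dos, spec = spec, rs = rs, ops = ops)
}

test_that("model validation enforces w in (0,1) and positive definiteness", {
  expect_error(model_spec(traits = "t", G0 = 1, R0 = 1, w = 0),
               "strictly between")
  expect_error(model_spec(traits = "t", G0 = 1, R0 = 1, w = 1),
               "strictly between")
  expect_error(model_spec(traits = "t", G0 = -1, R0 = 1, w = 0.5),
               "positive definite")
  expect_error(model_spec(traits = c("a", "b"), maternal = TRUE,
                          G0 = diag(4), R0 = matrix(c(1, 2, 2, 1), 2),
                          w = 0.5), "R0")
})

test_that("record validation rejects unknown animals and drops missing y", {
  fx <- uni_fixture()
  df <- data.frame(trait = "t1", y = 1, animal = 9L, herd = 1L)
  expect_error(record_set(df, fx$spec, fx$ped), "out of pedigree range")
  df2 <- data.frame(trait = "t1", y = c(1, NA), animal = c(1L, 2L),
                    herd = 1L)
  expect_message(rs <- record_set(df2, fx$spec, fx$ped), "dropped")
  expect_equal(rs$n, 1L)
  df3 <- data.frame(trait = "zz", y = 1, animal = 1L, herd = 1L)
  expect_error(record_set(df3, fx$spec, fx$ped), "not in the model")
})

test_that("split operator equals the dense block-formula oracle (univariate)", {
  fx <- uni_fixture()
  for (v in c("ms", "liu")) {
    sys <- assemble_system(fx$spec, fx$rs, fx$ops, fx$pg, variant = v)
    oracle <- dense_oracle(fx$spec, fx$rs, fx$ped, fx$dos, v)
    expect_equal(sys$map$total, nrow(oracle$C))
    Cimpl <- dense_from_matvec(sys)
    expect_lt(max(abs(Cimpl - oracle$C)), 1e-10 * max(1, max(abs(oracle$C))))
    expect_lt(max(abs(sys$b - oracle$b)), 1e-12)
  }
})

test_that("right-hand sides follow the printed definitions", {
  fx <- uni_fixture()
  sys_liu <- assemble_system(fx$spec, fx$rs, fx$ops, fx$pg, variant = "liu")
  m <- sys_liu$map
  expect_equal(sys_liu$b[(m$off_g + 1L):m$total], rep(0, m$n_snp))
  sys_ms <- assemble_system(fx$spec, fx$rs, fx$ops, fx$pg, variant = "ms")
  # SNP block of b_MS = Z' W_g' R_g^-1 y_g, assembled densely here
  zc <- dense_center(fx$dos)
  rinv <- 1 / 2.0
  wg_r_y <- c(rinv * fx$rs$y[1],                      # animal 1
              rinv * (fx$rs$y[3] + fx$rs$y[4]))       # animal 3
  expect_equal(sys_ms$b[(m$off_g + 1L):m$total],
               as.numeric(t(zc$Z) %*% wg_r_y))
})

test_that("split operator matches the oracle on a bivariate maternal model", {
  ds <- tiny_bivariate()
  ops <- extract_ancestor_blocks(ds$ped, account_inbreeding = TRUE)
  dos <- unpack_genotypes(ds$pg)
  for (v in c("ms", "liu")) {
    sys <- assemble_system(ds$spec, ds$rs, ops, ds$pg, variant = v)
    oracle <- dense_oracle(ds$spec, ds$rs, ds$ped, dos, v)
    expect_equal(sys$map$total, nrow(oracle$C))
    set.seed(5)
    for (k in 1:20) {
      x <- rnorm(sys$map$total)
      ref <- as.numeric(oracle$C %*% x)
      expect_lt(max(abs(system_matvec(sys, x) - ref)),
                1e-10 * max(1, max(abs(ref))))
    }
    expect_lt(max(abs(sys$b - oracle$b)), 1e-10)
    # symmetry of the full operator
    x <- rnorm(sys$map$total); y <- rnorm(sys$map$total)
    s1 <- sum(system_matvec(sys, x) * y)
    s2 <- sum(x * system_matvec(sys, y))
    expect_lt(abs(s1 - s2) / max(1, abs(s2)), 1e-10)
    expect_equal(system_matvec(sys, numeric(sys$map$total)),
                 numeric(sys$map$total))
  }
})

test_that("J covariates satisfy their defining equation", {
  # all animals genotyped -> j is identically -1
  pall <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = rep(TRUE, 3))
  expect_equal(j_covariates(extract_ancestor_blocks(pall)), rep(-1, 3))
  # trio with genotyped offspring: dense-solve values for the founders
  trio <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = c(FALSE, FALSE, TRUE))
  ops <- extract_ancestor_blocks(trio)
  j <- j_covariates(ops)
  Ainv <- ssnpblup:::crs3_to_dense(ops$a_inv_full)
  jn_dense <- solve(Ainv[1:2, 1:2], Ainv[1:2, 3] %*% matrix(1))
  expect_equal(j[1:2], as.numeric(jn_dense))
  expect_equal(j[3], -1)
  # residual of the defining equation on a larger random pedigree
  ped <- rand_ped(150, geno_frac = 0.3, seed = 8)
  ops2 <- extract_ancestor_blocks(ped)
  j2 <- j_covariates(ops2)
  expect_lt(max(abs(ops2$Ann %*% j2[ops2$n_index] -
                      ops2$Ang %*% rep(1, ops2$n_g))), 1e-10)
})

test_that("MS and Liu are reparameterisations of the same model", {
  ds <- tiny_bivariate()
  ops <- extract_ancestor_blocks(ds$ped, account_inbreeding = TRUE)
  sys_ms <- assemble_system(ds$spec, ds$rs, ops, ds$pg, variant = "ms")
  sys_liu <- assemble_system(ds$spec, ds$rs, ops, ds$pg, variant = "liu")
  x_ms <- solve(dense_from_matvec(sys_ms), sys_ms$b)
  x_liu <- solve(dense_from_matvec(sys_liu), sys_liu$b)
  eq <- solutions_equivalent(sys_ms, x_ms, sys_liu, x_liu,
                             rel_resid_ms = 1e-14, rel_resid_liu = 1e-14,
                             resid_tol = 1e-8)
  expect_true(eq$comparable)
  expect_lt(eq$max_abs_ug_diff, 1e-6)
  expect_lt(eq$max_abs_fixed_diff, 1e-6)
  expect_lt(eq$max_abs_g_diff, 1e-6)
  expect_gt(eq$cor_ug, 0.999999)
  # unsolved inputs flagged non-comparable
  eq_bad <- solutions_equivalent(sys_ms, x_ms, sys_liu, x_liu,
                                 rel_resid_ms = 1e-2, rel_resid_liu = 1e-14,
                                 resid_tol = 1e-8)
  expect_false(eq_bad$comparable)
})

test_that("w -> 1 approaches pedigree BLUP and shrinks SNP effects to zero", {
  ds <- tiny_dataset("w1", n_founders = 20L, n_generations = 2L,
                     offspring_per_mating = 2L, n_snp = 25L,
                     genotyping_rate = c(0, 0.4, 0.6),
                     fixed_levels = c(hys = 3L), fixed_sd = c(hys = 1),
                     missing_rate = 0, seed = 303L)
  spec <- ds$spec; spec$w <- 0.999
  ops <- extract_ancestor_blocks(ds$ped, account_inbreeding = TRUE)
  sys <- assemble_system(spec, ds$rs, ops, ds$pg, variant = "liu")
  x <- solve(dense_from_matvec(sys), sys$b)
  dos <- unpack_genotypes(ds$pg)
  pblup <- dense_pedigree_blup(spec, ds$rs, ds$ped, dos)
  # genetic effects of all animals agree with the pedigree-only solve
  m <- sys$map
  u_ss <- rbind(ssnpblup:::blk_mat(x[(m$off_un + 1L):m$off_ag], m$q),
                genotyped_breeding_values(sys, x))
  u_pb <- rbind(pblup$u[ops$n_index, , drop = FALSE],
                pblup$u[ops$g_index, , drop = FALSE])
  scale <- max(abs(u_pb))
  expect_lt(max(abs(u_ss - u_pb)) / scale, 1e-3)
  # SNP effects collapse
  g <- x[(m$off_g + 1L):m$total]
  expect_lt(max(abs(g)), 1e-3 * scale)
})
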