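test_that("Henderson A-inverse reproduces the small closed-form cases", {
  # single founder
  p1 <- pedigree(sire = 0, dam = 0)
  expect_equal(ssnpblup:::crs3_to_dense(build_a_inverse(p1)), matrix(1))
  # trio: two founders and their offspring
  trio <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2))
  expect_equal(ssnpblup:::crs3_to_dense(build_a_inverse(trio)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3))
  # founder + offspring with unknown dam: inverse of [[1,.5],[.5,1]]
  pair <- pedigree(sire = c(0, 1), dam = c(0, 0))
  expect_equal(ssnpblup:::crs3_to_dense(build_a_inverse(pair)),
               matrix(c(4, -2, -2, 4) / 3, 2))
})

test_that("pedigree validation rejects malformed input", {
  expect_error(pedigree(sire = c(2, 0, 0), dam = c(0, 0, 0)),
               "not topologically")
  expect_error(pedigree(sire = c(0, 5), dam = c(0, 0)), "out of range")
  expect_error(pedigree(sire = c(1, 0), dam = c(0, 0)), "own parent")
})

test_that("inbreeding-aware A-inverse inverts the tabular A exactly", {
  for (seed in 1:3) {
    ped <- rand_ped(120, seed = seed)
    A <- tab_A(ped$sire, ped$dam)
    ai <- ssnpblup:::crs3_to_dense(build_a_inverse(ped,
                                                   account_inbreeding = TRUE))
    expect_lt(max(abs(ai - solve(A))), 1e-9)
    expect_equal(inbreeding_coefficients(ped), diag(A) - 1)
  }
})

test_that("ancestor closure and block extraction behave on trios", {
  trio_geno_off <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                            genotyped = c(FALSE, FALSE, TRUE))
  ops <- extract_ancestor_blocks(trio_geno_off)
  expect_equal(ops$anc_index, 1:3)      # parents are ancestors
  trio_geno_sire <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                             genotyped = c(TRUE, FALSE, FALSE))
  ops2 <- extract_ancestor_blocks(trio_geno_sire)
  expect_equal(ops2$anc_index, 1L)      # a founder has no ancestors
  expect_equal(as.matrix(ops2$a_gg_anc), matrix(1))
  expect_error(extract_ancestor_blocks(
    pedigree(sire = 0, dam = 0)), "no genotyped")
})

test_that("A_gg^-1 via ancestor blocks equals the dense pedigree oracle", {
  for (seed in 1:3) {
    ped <- rand_ped(200, geno_frac = 0.25, seed = 10 + seed)
    ops <- extract_ancestor_blocks(ped, account_inbreeding = TRUE)
    A <- tab_A(ped$sire, ped$dam)
    gi <- which(ped$genotyped)
    expect_lt(max(abs(agg_inv_matmat(ops, diag(ops$n_g)) -
                        solve(A[gi, gi]))), 1e-10)
  }
})

test_that("Delta holds exactly the non-ancestor offspring contributions", {
  # genotyped founder with one non-genotyped terminal offspring:
  # A^gg - A^gg_anc = 4/3 - 1 = 1/3
  ped <- pedigree(sire = c(0, 1), dam = c(0, 0),
                  genotyped = c(TRUE, FALSE))
  expect_equal(ssnpblup:::crs3_to_dense(build_delta(ped)), matrix(1 / 3))
  # no non-genotyped offspring of genotyped animals -> Delta = 0
  ped0 <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = c(FALSE, FALSE, TRUE))
  expect_equal(crs3_nnz(build_delta(ped0)), 0L)
  # random pedigrees: Delta = A^gg - A^gg_anc from the two full builds
  for (seed in 1:3) {
    ped <- rand_ped(150, geno_frac = 0.3, seed = 20 + seed)
    ops <- extract_ancestor_blocks(ped)
    gg_full <- as.matrix(ops$Agg)
    expect_lt(max(abs(ssnpblup:::crs3_to_dense(ops$delta) -
                        (gg_full - as.matrix(ops$a_gg_anc)))), 1e-12)
  }
})

test_that("Q operator: trivial, trio and dual-route cases", {
  # all animals genotyped -> no non-genotyped ancestors -> Q = 0
  pall <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = rep(TRUE, 3))
  ops <- extract_ancestor_blocks(pall)
  expect_equal(q_matmat(ops, diag(3)), matrix(0, 3, 3))
  # trio with genotyped offspring: Q = A^gg - A_gg^-1 (dense oracle)
  trio <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = c(FALSE, FALSE, TRUE))
  opst <- extract_ancestor_blocks(trio)
  A <- tab_A(trio$sire, trio$dam)
  expect_equal(q_matmat(opst, matrix(1)),
               as.matrix(opst$Agg) - solve(A[3, 3, drop = FALSE]))
  # random pedigree: ancestor+Delta route vs direct full-pedigree route
  for (seed in 1:3) {
    ped <- rand_ped(100, geno_frac = 0.2, seed = 30 + seed)
    ops <- extract_ancestor_blocks(ped, account_inbreeding = TRUE)
    Ainv <- solve(tab_A(ped$sire, ped$dam))
    gi <- which(ped$genotyped); ni <- which(!ped$genotyped)
    Qdirect <- Ainv[gi, ni] %*% solve(Ainv[ni, ni], Ainv[ni, gi])
    expect_lt(max(abs(q_matmat(ops, diag(ops$n_g)) - Qdirect)), 1e-10)
  }
})

test_that("A_gg^-1 + Q = A^gg on random pedigrees up to n = 500", {
  for (n in c(120, 500)) {
    ped <- rand_ped(n, geno_frac = 0.2, seed = n)
    ops <- extract_ancestor_blocks(ped)
    V <- matrix(rnorm(ops$n_g * 3), ops$n_g)
    lhs <- agg_inv_matmat(ops, V) + q_matmat(ops, V)
    rhs <- as.matrix(ops$Agg %*% V)
    expect_lt(max(abs(lhs - rhs)), 1e-10 * max(1, max(abs(rhs))))
  }
})

test_that("Monte-Carlo diag(A_gg^-1): exactness, determinism, accuracy, bias", {
  # single genotyped founder: estimate exact for any sample count
  p1 <- pedigree(sire = c(0, 1), dam = c(0, 0),
                 genotyped = c(TRUE, FALSE))
  ops1 <- extract_ancestor_blocks(p1)
  expect_equal(mc_diag_agg_inverse(ops1, n_samples = 3, seed = 5),
               1)  # A_gg = A[1,1] = 1, probes square to one
  # determinism
  ped <- rand_ped(150, geno_frac = 0.35, seed = 44)
  ops <- extract_ancestor_blocks(ped)
  expect_identical(mc_diag_agg_inverse(ops, 200, seed = 9),
                   mc_diag_agg_inverse(ops, 200, seed = 9))
  # accuracy at s = 10^4 on ~50 genotyped animals
  exact <- diag(agg_inv_matmat(ops, diag(ops$n_g)))
  est <- mc_diag_agg_inverse(ops, n_samples = 1e4, seed = 2)
  expect_lt(max(abs(est - exact) / exact), 0.05)
  # unbiasedness: averaging across seeds converges
  many <- rowMeans(vapply(1:40, function(s)
    mc_diag_agg_inverse(ops, n_samples = 200, seed = s),
    numeric(ops$n_g)))
  expect_lt(max(abs(many - exact) / exact),
            max(abs(est - exact) / exact) + 0.05)
})

test_that("genotyped parent-link count matches brute force", {
  none <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = c(FALSE, FALSE, TRUE))
  expect_equal(count_genotyped_parent_links(none), 0L)
  both <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2),
                   genotyped = c(TRUE, TRUE, FALSE))
  expect_equal(count_genotyped_parent_links(both), 2L)
  expect_equal(count_genotyped_parent_links(both, distinct = TRUE), 1L)
  ped <- rand_ped(200, geno_frac = 0.4, seed = 77)
  brute <- sum(vapply(seq_len(ped$n), function(i) {
    (ped$sire[i] > 0 && ped$genotyped[ped$sire[i]]) +
      (ped$dam[i] > 0 && ped$genotyped[ped$dam[i]])
  }, 0))
  expect_equal(count_genotyped_parent_links(ped), brute)
})

test_that("pedigree file loader renumbers to a topological order", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("animal sire dam genotyped",
               "kid sire1 dam1 1",
               "sire1 0 0 0",
               "dam1 0 NA 1",
               "kid2 kid dam1 0"), f)
  ped <- read_pedigree(f)
  expect_equal(ped$n, 4L)
  idx <- attr(ped, "id_map")
  expect_true(idx[["sire1"]] < idx[["kid"]] && idx[["dam1"]] < idx[["kid"]])
  expect_true(idx[["kid"]] < idx[["kid2"]])
  expect_equal(sum(ped$genotyped), 2L)
  # cycle detection
  writeLines(c("animal sire dam", "a b 0", "b a 0"), f)
  expect_error(read_pedigree(f), "cycle")
})
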