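#' Simulation configuration
#'
#' The stated world of the bundled synthetic data: a multi-generation,
#' non-overlapping pedigree with random mating; Mendelian gene dropping
#' from founder allele frequencies; a genotyped subset concentrated in
#' recent generations; and phenotypes from the bivariate direct+maternal
#' linear mixed model the solver fits (fixed effects, polygenic effects
#' with residual polygenic fraction `w`, SNP effects, permanent
#' environment of the dam, residual). Defaults give roughly 3,000
#' animals, ~600 genotyped and 1,000 SNPs — large enough to exercise
#' every operator, small enough to solve in minutes on one CPU.
#'
#' @param n_founders Founder cohort size (default 300).
#' @param n_generations Number of discrete offspring generations (6).
#' @param offspring_per_mating Offspring per dam-sire pair (3).
#' @param genotyping_rate Per-generation genotyping probability, founders
#'   first; recycled/truncated to `n_generations + 1` entries. The
#'   default rises over generations, as in routine evaluations where
#'   young animals are genotyped more densely.
#' @param n_snp Number of SNPs (1000).
#' @param founder_freq_range Founder allele frequencies are drawn
#'   uniformly from this interval (default (0.05, 0.95)).
#' @param missing_rate Genotype call missingness injected into the
#'   genotyped subset (default 0.01).
#' @param traits,G0,R0,P0,w True model parameters; defaults: two traits,
#'   four genetic channels (direct variance 1, maternal 0.5,
#'   direct-maternal correlation -0.3, between-trait correlation 0.8),
#'   residual variance 2 per trait, permanent environment variance 0.3
#'   (correlation 0.5), `w = 0.05`.
#' @param fixed_levels Named integer vector: levels per fixed class
#'   effect (default `c(hys = 60, ym = 8)`, a large herd-year-season-like
#'   effect plus a small one).
#' @param fixed_sd Effect-size standard deviation per fixed effect.
#' @param seed RNG seed; every generator output is reproducible given it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 300L, n_generations = 6L,
                       offspring_per_mating = 3L,
                       genotyping_rate = c(0, 0.05, 0.1, 0.15, 0.25,
                                           0.35, 0.5),
                       n_snp = 1000L,
                       founder_freq_range = c(0.05, 0.95),
                       missing_rate = 0.01,
                       traits = c("t1", "t2"),
                       G0 = NULL, R0 = NULL, P0 = NULL, w = 0.05,
                       fixed_levels = c(hys = 60L, ym = 8L),
                       fixed_sd = c(hys = 1.0, ym = 0.5),
                       seed = 1L) {
  nt <- length(traits)
  if (is.null(G0)) {
    dm <- matrix(c(1, -0.3 * sqrt(0.5), -0.3 * sqrt(0.5), 0.5), 2)
    tr <- diag(nt) * 0.2 + 0.8
    G0 <- kronecker(tr, dm)   # channel order: (trait, type), type fastest
  }
  if (is.null(R0)) R0 <- diag(2, nt)
  if (is.null(P0)) P0 <- 0.3 * (diag(nt) * 0.5 + 0.5)
  stopifnot(w > 0, w < 1,
            founder_freq_range[1] > 0, founder_freq_range[2] < 1,
            all(diag(as.matrix(G0)) > 0), all(diag(as.matrix(R0)) > 0))
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 offspring_per_mating = as.integer(offspring_per_mating),
                 genotyping_rate = rep_len(genotyping_rate,
                                           n_generations + 1L),
                 n_snp = as.integer(n_snp),
                 founder_freq_range = founder_freq_range,
                 missing_rate = missing_rate,
                 traits = traits, G0 = as.matrix(G0), R0 = as.matrix(R0),
                 P0 = as.matrix(P0), w = w,
                 fixed_levels = fixed_levels, fixed_sd = fixed_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Non-overlapping generations: each generation pairs every dam of the
#' previous one with a randomly drawn sire (sires may repeat), and each
#' pair leaves `offspring_per_mating` offspring with random sex.
#' Genotyped flags are drawn per generation at the configured rate. The
#' output is topologically sorted by construction.
#'
#' @param cfg A [sim_config].
#' @return A [pedigree] with attributes `generation` and `sex`
#'   (`TRUE` = female).
#' @export
simulate_pedigree <- function(cfg) {
  with_seed(cfg$seed, {
    n0 <- cfg$n_founders
    sire <- integer(n0); dam <- integer(n0)
    gen <- rep(0L, n0)
    female <- sample(rep_len(c(TRUE, FALSE), n0))
    n_matings <- max(1L, n0 %/% 2L)   # constant cohort size per generation
    for (g in seq_len(cfg$n_generations)) {
      prev <- which(gen == g - 1L)
      dams <- prev[female[prev]]
      sires_pool <- prev[!female[prev]]
      if (!length(dams) || !length(sires_pool)) break
      if (length(dams) > n_matings) dams <- sample(dams, n_matings)
      s_of <- sample(sires_pool, length(dams), replace = TRUE)
      noff <- length(dams) * cfg$offspring_per_mating
      sire <- c(sire, rep(s_of, each = cfg$offspring_per_mating))
      dam <- c(dam, rep(dams, each = cfg$offspring_per_mating))
      gen <- c(gen, rep(g, noff))
      female <- c(female, sample(rep_len(c(TRUE, FALSE), noff)))
    }
    n <- length(sire)
    genotyped <- stats::runif(n) < cfg$genotyping_rate[gen + 1L]
    ped <- pedigree(sire = sire, dam = dam, genotyped = genotyped,
                    original_id = sprintf("A%05d", seq_len(n)))
    attr(ped, "generation") <- gen
    attr(ped, "sex_female") <- female
    ped
  })
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are Bernoulli draws at per-SNP frequencies sampled
#' from `founder_freq_range`; each offspring allele is a uniform draw
#' from the corresponding parent's two alleles (an unknown parent
#' contributes a fresh population draw). No mutation, no linkage: SNPs
#' are independent. The packed store covers the genotyped subset only
#' (with optional missing-call injection); the full true dosage matrix is
#' kept for phenotype simulation and parameter-recovery checks.
#'
#' @param ped A [pedigree] from [simulate_pedigree()].
#' @param cfg The same [sim_config].
#' @return List: `pg` ([packed_genotypes], genotyped subset),
#'   `true_dosage` (n x n_snp integer, all animals), `founder_freq`,
#'   `m_true` (2 sum p(1-p) over observed full-population frequencies).
#' @export
drop_genotypes <- function(ped, cfg) {
  with_seed(cfg$seed + 1L, {
    n <- ped$n; ns <- cfg$n_snp
    fq <- stats::runif(ns, cfg$founder_freq_range[1],
                       cfg$founder_freq_range[2])
    h1 <- matrix(0L, n, ns); h2 <- matrix(0L, n, ns)
    pop_draw <- function() as.integer(stats::runif(ns) < fq)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      h1[i, ] <- if (s > 0L) {
        pick <- stats::runif(ns) < 0.5
        ifelse(pick, h1[s, ], h2[s, ])
      } else pop_draw()
      h2[i, ] <- if (d > 0L) {
        pick <- stats::runif(ns) < 0.5
        ifelse(pick, h1[d, ], h2[d, ])
      } else pop_draw()
    }
    dose <- h1 + h2
    p_obs <- colMeans(dose) / 2
    gidx <- which(ped$genotyped)
    sub <- dose[gidx, , drop = FALSE]
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(length(sub)) < cfg$missing_rate,
                     nrow(sub))
      sub[miss] <- NA_integer_
    }
    pg <- pack_genotypes(sub, animal_ids = ped$original_id[gidx])
    list(pg = pg, true_dosage = dose, founder_freq = fq,
         m_true = 2 * sum(p_obs * (1 - p_obs)))
  })
}

#' Simulate phenotypes under the single-step model
#'
#' True SNP effects per SNP are `N_q(0, (1-w)/m * G0)` with `m` the
#' observed-frequency scaling constant of the dropped genotypes, so the
#' simulated SNP-explained variance matches the solver's prior scale.
#' Residual polygenic effects follow the pedigree recursion
#' `a_i = (a_s + a_d)/2 + phi_i` with Mendelian-sampling variance
#' `d_i * w * G0`. Total breeding values are `u = a + Z_full g` with
#' `Z_full` the centered true dosage of all animals. Every non-founder
#' receives one record on a randomly assigned trait:
#' `y = fixed + u_direct(self) + u_maternal(dam) + pe(dam) + e`.
#'
#' @param ped,geno,cfg Pedigree, [drop_genotypes()] output, config.
#' @return List: `records` (data frame ready for [record_set()]),
#'   `truth` (true `u`, `a`, `g`, `pe`, fixed effects).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  with_seed(cfg$seed + 2L, {
    nt <- length(cfg$traits); ntypes <- 2L
    q <- nt * ntypes
    n <- ped$n; ns <- cfg$n_snp
    w <- cfg$w
    G0 <- cfg$G0
    cG <- chol(G0)
    # SNP effects and genomic part of u
    g_true <- matrix(stats::rnorm(ns * q), ns, q) %*%
      (cG * sqrt((1 - w) / geno$m_true))
    p_obs <- colMeans(geno$true_dosage) / 2
    Zfull <- sweep(geno$true_dosage, 2L, 2 * p_obs)
    u_snp <- Zfull %*% g_true
    # residual polygenic part by pedigree recursion
    a <- matrix(0, n, q)
    dvec <- 1 / mendelian_alpha(ped)
    phi <- matrix(stats::rnorm(n * q), n, q) %*% (cG * sqrt(w))
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      pa <- (if (s > 0L) a[s, ] else 0) + (if (d > 0L) a[d, ] else 0)
      a[i, ] <- pa / 2 + sqrt(dvec[i]) * phi[i, ]
    }
    u <- a + u_snp
    # permanent environment of each dam
    pe <- matrix(stats::rnorm(n * nt), n, nt) %*% chol(cfg$P0)
    # fixed effects
    fe <- lapply(names(cfg$fixed_levels), function(e)
      stats::rnorm(cfg$fixed_levels[[e]], sd = cfg$fixed_sd[[e]]))
    names(fe) <- names(cfg$fixed_levels)
    gen <- attr(ped, "generation")
    rec_an <- which(gen > 0L)         # all non-founders: dam always known
    nrec <- length(rec_an)
    trait <- sample.int(nt, nrec, replace = TRUE)
    dams <- ped$dam[rec_an]
    fixed_cols <- lapply(names(cfg$fixed_levels), function(e)
      sample.int(cfg$fixed_levels[[e]], nrec, replace = TRUE))
    names(fixed_cols) <- names(cfg$fixed_levels)
    ch_d <- (trait - 1L) * ntypes + 1L
    ch_m <- ch_d + 1L
    y <- u[cbind(rec_an, ch_d)] + u[cbind(dams, ch_m)] +
      pe[cbind(dams, trait)] +
      stats::rnorm(nrec, sd = sqrt(diag(cfg$R0)[trait]))
    for (e in names(fe)) y <- y + fe[[e]][fixed_cols[[e]]]
    records <- data.frame(trait = cfg$traits[trait], y = y,
                          animal = rec_an, dam = dams,
                          stringsAsFactors = FALSE)
    for (e in names(fixed_cols)) records[[e]] <- fixed_cols[[e]]
    list(records = records,
         truth = list(u = u, a = a, g = g_true, pe = pe, fixed = fe,
                      m_true = geno$m_true))
  })
}

#' One-call synthetic dataset
#'
#' Runs [simulate_pedigree()], [drop_genotypes()] and
#' [simulate_phenotypes()], builds the matching [model_spec], and
#' optionally writes the whole dataset to disk via [write_dataset()].
#'
#' @param cfg A [sim_config].
#' @param dir Output directory (`NULL` = in-memory only).
#' @return List: `ped`, `geno`, `pg`, `records`, `truth`, `spec`, `cfg`,
#'   and `paths` when written.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, geno, cfg)
  spec <- model_spec(traits = cfg$traits, maternal = TRUE,
                     fixed_class = names(cfg$fixed_levels),
                     pe = TRUE, G0 = cfg$G0, R0 = cfg$R0, P0 = cfg$P0,
                     w = cfg$w)
  out <- list(ped = ped, geno = geno, pg = geno$pg, records = ph$records,
              truth = ph$truth, spec = spec, cfg = cfg)
  if (!is.null(dir)) out$paths <- write_dataset(dir, out)
  out
}

#' Write a simulated dataset to disk
#'
#' Emits pedigree text, a PLINK 1 binary triplet, the phenotype table, a
#' per-animal truth table and a ready-to-run JSON configuration. The
#' files round-trip bit-exactly through [read_pedigree()], [read_bed()]
#' and [read_records()].
#'
#' @param dir Output directory (created if needed).
#' @param ds A [simulate_dataset()] result (or compatible list).
#' @return Named character vector of paths.
#' @export
write_dataset <- function(dir, ds) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- ds$ped
  pedfile <- file.path(dir, "pedigree.tsv")
  utils::write.table(
    data.frame(animal = ped$original_id,
               sire = ifelse(ped$sire > 0L, ped$original_id[pmax(ped$sire, 1L)], "0"),
               dam = ifelse(ped$dam > 0L, ped$original_id[pmax(ped$dam, 1L)], "0"),
               genotyped = as.integer(ped$genotyped)),
    pedfile, sep = "\t", quote = FALSE, row.names = FALSE)
  prefix <- file.path(dir, "genotypes")
  write_bed(ds$pg, prefix)
  rec <- ds$records
  rec$animal <- ped$original_id[rec$animal]
  rec$dam <- ifelse(rec$dam > 0L, ped$original_id[pmax(rec$dam, 1L)], "0")
  phenofile <- file.path(dir, "phenotypes.tsv")
  utils::write.table(rec, phenofile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truthfile <- file.path(dir, "truth.tsv")
  tu <- data.frame(animal = ped$original_id, ds$truth$u)
  names(tu)[-1L] <- paste0("u_", ds$spec$channels)
  utils::write.table(tu, truthfile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfgfile <- file.path(dir, "config.json")
  cfg_out <- list(
    paths = list(pedigree = "pedigree.tsv", bed = "genotypes.bed",
                 phenotypes = "phenotypes.tsv"),
    model = list(traits = ds$spec$traits, maternal = ds$spec$maternal,
                 fixed_class = ds$spec$fixed_class,
                 covariates = ds$spec$covariates,
                 j_covariates = ds$spec$j_covariates, pe = ds$spec$pe,
                 G0 = ds$spec$G0, R0 = ds$spec$R0, P0 = ds$spec$P0,
                 w = ds$spec$w),
    solver = list(variant = "liu", tol = 1e-6, max_iter = 5000,
                  mc_samples = 1000, seed = 1))
  jsonlite::write_json(cfg_out, cfgfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(pedigree = pedfile, bed = paste0(prefix, ".bed"),
    bim = paste0(prefix, ".bim"), fam = paste0(prefix, ".fam"),
    phenotypes = phenofile, truth = truthfile, config = cfgfile)
}
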