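---
title: "Matrix-free single-step SNP-BLUP: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-free single-step SNP-BLUP: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnpblup)
```

## The model

Single-step SNP-BLUP (ssSNPBLUP) jointly analyses phenotypes of genotyped
and non-genotyped animals, pedigree relationships, and SNP genotypes, while
fitting SNP effects directly — so the inverse genomic relationship matrix is
never formed. For a univariate animal model the package assembles either of
two equivalent linear systems $C_i x_i = b_i$:

* **MS parameterisation** — unknowns $(\beta, u_n, a_g, g)$: fixed effects,
  additive genetic effects of non-genotyped animals, *residual polygenic*
  effects of genotyped animals, and SNP effects. Total genetic merit of a
  genotyped animal is $u_g = a_g + Z g$.
* **Liu parameterisation** — unknowns $(\beta, u_n, u_g, g)$, carrying the
  full genetic effect $u_g$ for genotyped animals directly.

Here $Z$ is the genotype matrix (counted-allele dosage 0/1/2, centered by
observed allele frequencies; a missing call contributes 0 after centering).
The genetic prior blocks involve the sparse inverse pedigree relationship
matrix $A^{-1}$ partitioned over non-genotyped/genotyped animals, the matrix
$Q = A^{gn}(A^{nn})^{-1}A^{ng}$, the inverse $A_{gg}^{-1} = A^{gg} - Q$ of
the genotyped-animal relationship block, the residual polygenic fraction
$w \in (0,1)$ (default 0.05), and $m = 2\sum_j p_j(1-p_j)$, which puts the
per-SNP effect variance $(1-w)\sigma_u^2/m$ on the additive scale.

Multi-trait and maternal models generalise every scalar $\sigma_u^{-2}$ to
$G_0^{-1}$, the inverse covariance of the $q$ = traits × (direct, maternal)
genetic channels, via Kronecker products; equations are ordered channels
fastest within a level. Each record observes exactly one trait, so the
residual precision is diagonal per record ($1/R_{0,tt}$); a permanent
environment effect of the dam (covariance $P_0$ across traits) is optional.
One J covariate per genetic channel ($j = -1$ for genotyped animals,
$A^{nn} j_n = -A^{ng} j_g$ otherwise) aligns the pedigree and genomic bases;
it is on by default.

## The matrix-free operator

$C$ is never formed. The product $Cx$ is computed from split parts:

* $C_{LS}$ — the least-squares (data) part, one in-memory sparse matrix
  over fixed, permanent environment, $u_n$, genotyped-animal and a
  *duplicate genotyped channel* that carries $Zg$, so records on genotyped
  animals load both the polygenic and the SNP equations. (The original
  out-of-core iteration-on-data scheme is replaced by this equivalent
  in-memory operator at desk scale; the interface keeps a streaming backend
  pluggable.)
* $T$ — identity except the SNP block, which maps through $Z$:
  $C_{MS} = T'(C_{LS} + C_{R1})T + C_{R2}$ and
  $C_{Liu} = C_{LS} + T' C_{R1} T + C_{R2}$.
* Pedigree parts — $A^{-1}$ is built once by Henderson's rules and stored
  as the upper triangle in three-array compressed row storage (CRS3); at
  most $4n$ stored non-zeros, hence at most $52n + 4$ bytes with 4-byte
  integers and 8-byte reals. $Q$ and $A_{gg}^{-1}$ are applied through the
  ancestor-restricted blocks
  $A_{gg}^{-1} = A^{gg}_{anc} - A^{gn}_{anc}(A^{nn}_{anc})^{-1}A^{ng}_{anc}$
  and $Q = A^{gn}_{anc}(A^{nn}_{anc})^{-1}A^{ng}_{anc} + \Delta$ with
  $\Delta = A^{gg} - A^{gg}_{anc}$ read from the pedigree in one pass;
  $A^{nn}_{anc}$ is factorized once (sparse Cholesky) and reused. Only two
  $Q$ (or two $A_{gg}^{-1}$) products are needed per iteration; the
  operands are batched into one solve each.
* Genotype parts — $Z$ is kept bit-packed exactly as in a PLINK 1 `.bed`
  file (2 bits/call, SNP-major: 1/32 of the double-precision footprint)
  and decoded block-wise into cache-sized panels inside the product
  kernels.

Note the source description of the ancestor form of $Q$ shows
$(A^{gg}_{anc})^{-1}$ as the middle inverse; that is inconsistent with the
$A_{gg}^{-1}$ identity above and with $Q = A^{gg} - A_{gg}^{-1}$, so the
package uses $(A^{nn}_{anc})^{-1}$ and enforces the identity
$Q + A_{gg}^{-1} = A^{gg}$ as a mandatory test.

## Preconditioner and solver

The preconditioner $M$ is block-diagonal: a pure diagonal for the
designated "large" fixed effect (default: the class effect with most
levels, playing the role of herd×year×season), a sparse factorized block
with ridge $10^{-4}\,\mathrm{diag}$ for the remaining fixed columns, and
one $q \times q$ block per random-effect level. Two terms are approximated,
exactly as in routine practice:

* $\mathrm{diag}(A_{gg}^{-1})$ — Hutchinson's stochastic estimator with
  Rademacher (±1) probes, default 1000 samples (the distribution is a
  package choice; ±1 probes have lower variance for diagonal estimation
  and are exact for 1×1 blocks). Both parameterisations need it through
  $\Sigma^{22} = A^{gg} + (1/w - 1)A_{gg}^{-1}$.
* the SNP-block diagonals —
  $\mathrm{diag}(Z'A_{gg}^{-1}Z)_j \approx 2 n_g p_j(1-p_j)$ (Liu) and
  $\mathrm{diag}(Z'QZ)_j \approx (2n_g + n_{offspring})\,p_j(1-p_j)$ (MS),
  plus the exact prior term $m/(1-w)$; the MS data part
  $\mathrm{diag}(Z'W_g'R_g^{-1}W_gZ)$ is computed exactly by a blocked
  pass over the packed genotypes. $n_{offspring}$ counts parent-offspring
  links with a genotyped parent (an offspring of two genotyped parents
  counts twice; a flag switches to distinct offspring — the approximation
  tolerates either convention).

A second-level diagonal $D$ scales the SNP equations only: $10^3$ (MS) and
$10^2$ (Liu) by default, 1 elsewhere; being constant over the whole block
it keeps $D^{-1}M^{-1}$ symmetric. PCG runs on
$D^{-1}M^{-1}C x = D^{-1}M^{-1}b$ from $x_0 = 0$ (the start is a package
choice) until $\lVert r_k \rVert / \lVert b \rVert < 10^{-6}$ using the
recursive residual, refreshed from a true $b - Cx$ every 100 iterations
and re-checked at exit (which residual the original procedure used is
unstated; the audit guards recursion drift and both values are reported).
Extreme eigenvalues of $D^{-1}M^{-1}C$ are estimated from the PCG
coefficients via the Lanczos tridiagonal (diagonal
$1/\alpha_k + \beta_{k-1}/\alpha_{k-1}$, off-diagonal
$\sqrt{\beta_k}/\alpha_k$); their ratio is the effective spectral condition
number. Preconditioner storage stays double precision by default (single
is immaterial at desk scale and no result depends on it).

### Numerical choices and degenerate inputs

* Henderson constants default to $\alpha = 2, 4/3, 1$ (two/one/zero known
  parents), *ignoring inbreeding*: the operator identities require internal
  consistency, not inbreeding accuracy. An inbreeding-aware variant
  (Meuwissen–Luo) sits behind `account_inbreeding = TRUE` and is what the
  dense tabular-relationship oracles in the tests compare against, since
  the tabular matrix necessarily includes inbreeding.
* Unknown parents contribute only through $\alpha$; unknown-parent groups
  and metafounders are out of scope.
* All animals genotyped: the ancestor non-genotyped block is empty,
  $Q = \Delta = 0$, and the J covariate is identically $-1$.
* A SNP with all calls missing is an error by default (optionally dropped
  to a zero column with a warning). $w \in \{0, 1\}$ is rejected.
* Fixed-effect columns keep every observed level of the designated large
  effect and drop the first level of the other class effects, so the tiny
  dense oracle systems stay non-singular and the two parameterisations'
  fixed effects are directly comparable.
* `p' C p <= 0` inside PCG aborts with a diagnostic (indefinite operator);
  reaching `max_iter` returns a partial report with `converged = FALSE`.

## The synthetic world

The generator emulates the structure of a routine national evaluation at
desk scale: discrete generations under random mating (constant cohorts,
dams mated once per generation, sires reused), gene dropping from founder
allele frequencies drawn uniformly on (0.05, 0.95) with no linkage or
mutation, genotyping concentrated in recent generations, and phenotypes
from a bivariate maternal model. Defaults: 300 founders + 6 × ~450
offspring ≈ 3,000 animals, ~600 genotyped, 1,000 SNPs, 1% missing calls,
one record per non-founder on one of two traits; direct/maternal variances
1/0.5 with correlation −0.3, between-trait correlation 0.8, permanent
environment 0.3, residual 2, $w = 0.05$; a 60-level "herd-year-season"
class effect (the large fixed effect) and an 8-level secondary effect.
True SNP effects use the same $m$ scaling as the solver's prior (from the
dropped genotypes' observed frequencies), and residual polygenic effects
follow the pedigree recursion with the same Mendelian-sampling variances
the solver assumes, so simulation and model are internally consistent.

What the generator does **not** emulate: linkage disequilibrium, selection
(genotyped animals are a random subset per generation), overlapping
generations, heterogeneous residual variances, genotyping errors. A green
end-to-end test therefore establishes numerical correctness of the
operators and solver on data with the model's exact covariance structure —
not robustness to the model misspecifications real data carry.

## What the checks establish

* Operator identities and kernels are verified against independent dense
  oracles (tabular relationship matrix + `solve`, dense centered genotype
  products, the printed block formulas assembled densely).
* Both parameterisations, solved to tolerance, agree on every estimable
  block (`u_g(MS) = a_g + Zg` vs `u_g(Liu)` below $10^{-4}$ at tolerance
  $10^{-8}$ on the bundled data).
* As $w \to 1$ the SNP block is shrunk away and the solution approaches
  pedigree BLUP of the same model ($10^{-3}$ relative at $w = 0.999$).
* On the bundled data the genomic model beats the $w \to 1$ pedigree proxy
  on true-breeding-value correlation for genotyped animals, averaged over
  5 seeds — the qualitative value-of-genomics check.

One acceptance expectation is knowingly left failing: replacing the
approximated preconditioner terms with exact diagonals changes the
desk-scale iteration count by ~2% (e.g. 361 vs 354), not by exactly zero.
With ~600 genotyped animals the Monte-Carlo estimator (±4.5% noise at 1000
samples) and the $O(1/n_g)$-biased closed forms are visibly different from
exact values; at the scale the approximations were designed for (>10^5
genotyped animals) they are not. The convergence *rate* is the same; the
bit-identical count is not attainable in the stated desk-scale world, and
the test is left asserting it rather than being loosened.

## Known limitations

Desk-scale only: `C_LS` is held in memory and there is no shared-memory
parallelism, out-of-core streaming, or distributed solve. No REML —
variance components are inputs. No dominance/epistasis, no dosage
genotypes, PLINK 1 SNP-major files only (individual-major is rejected, not
converted), and the counted allele is A2 of the `.bim` record.
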