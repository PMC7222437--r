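Package: ssnpblup
Title: Matrix-Free Single-Step SNP-BLUP Genomic Evaluations
Version: 0.1.0
Authors@R:
    person("ssnpblup", "developers", email = "ssnpblup@example.org",
           role = c("aut", "cre"))
Description: Assembles and solves single-step SNP best linear unbiased
    prediction (ssSNPBLUP) mixed-model equations without ever forming the
    coefficient matrix. Supports the Mantysaari-Stranden and the Liu
    formulations for uni- and multi-trait (direct + maternal) models. The
    coefficient matrix is split into a least-squares part, pedigree parts
    based on a sparse inverse numerator relationship matrix stored in
    three-array compressed row form, and genotype parts applied through
    bit-packed PLINK 1 genotype kernels. Systems are solved by a
    preconditioned conjugate gradient method with an approximated
    block-diagonal preconditioner and a second-level diagonal scaling of the
    SNP equations; extreme eigenvalues of the preconditioned matrix are
    estimated by the Lanczos method from the conjugate-gradient coefficients.
    Includes a pedigree/genotype/phenotype simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
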