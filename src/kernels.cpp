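#include <Rcpp.h>
using namespace Rcpp;

// Symmetric sparse matvec/matmat for the 3-array compressed-row (CRS3) store.
// Only the upper triangle (j >= i) is stored; every off-diagonal entry is
// applied twice. Indices are 1-based as handed over from R.
// [[Rcpp::export]]
NumericMatrix crs3_sym_matmat_cpp(IntegerVector ia, IntegerVector ja,
                                  NumericVector aa, NumericMatrix v) {
  const int n = ia.size() - 1;
  const int k = v.ncol();
  if (v.nrow() != n) stop("crs3 matvec: dimension mismatch");
  NumericMatrix y(n, k);
  for (int i = 0; i < n; ++i) {
    for (int p = ia[i] - 1; p < ia[i + 1] - 1; ++p) {
      const int j = ja[p] - 1;
      const double a = aa[p];
      for (int c = 0; c < k; ++c) {
        y(i, c) += a * v(j, c);
        if (j != i) y(j, c) += a * v(i, c);
      }
    }
  }
  return y;
}

// PLINK 1 .bed 2-bit code -> centered dosage value (missing -> 0).
// 0b00 = 0 copies of the counted (A2) allele, 0b01 = missing,
// 0b10 = 1 copy, 0b11 = 2 copies.
static inline double code_value(const int code, const double twop) {
  switch (code) {
  case 0: return -twop;
  case 1: return 0.0;
  case 2: return 1.0 - twop;
  default: return 2.0 - twop;
  }
}

// Pack an integer dosage matrix (n_g x n_snp, NA = missing) into SNP-major
// PLINK 1 2-bit codes. Trailing bits of the last byte per SNP are zero.
// [[Rcpp::export]]
RawVector plink_pack_cpp(IntegerMatrix dosages) {
  const int ng = dosages.nrow(), nsnp = dosages.ncol();
  const int bps = (ng + 3) / 4; // bytes per SNP
  RawVector codes((R_xlen_t)bps * nsnp);
  for (int j = 0; j < nsnp; ++j) {
    R_xlen_t off = (R_xlen_t)j * bps;
    for (int k = 0; k < ng; ++k) {
      int d = dosages(k, j);
      int code;
      if (d == NA_INTEGER) code = 1;
      else if (d == 0) code = 0;
      else if (d == 1) code = 2;
      else if (d == 2) code = 3;
      else stop("dosages must be 0, 1, 2 or NA");
      codes[off + k / 4] |= (Rbyte)(code << (2 * (k % 4)));
    }
  }
  return codes;
}

// Decode to an integer dosage matrix (NA = missing); used for allele
// frequency counting, round-trip tests and small dense extractions.
// [[Rcpp::export]]
IntegerMatrix plink_unpack_cpp(RawVector codes, int ng, int nsnp) {
  const int bps = (ng + 3) / 4;
  if ((R_xlen_t)bps * nsnp != codes.size()) stop("code array size mismatch");
  IntegerMatrix out(ng, nsnp);
  for (int j = 0; j < nsnp; ++j) {
    R_xlen_t off = (R_xlen_t)j * bps;
    for (int k = 0; k < ng; ++k) {
      int code = (codes[off + k / 4] >> (2 * (k % 4))) & 3;
      out(k, j) = (code == 1) ? NA_INTEGER : (code == 0 ? 0 : code - 1);
    }
  }
  return out;
}

// Per-SNP counted-allele totals: row 1 = sum of non-missing dosages,
// row 2 = number of non-missing calls.
// [[Rcpp::export]]
NumericMatrix plink_counts_cpp(RawVector codes, int ng, int nsnp) {
  const int bps = (ng + 3) / 4;
  if ((R_xlen_t)bps * nsnp != codes.size()) stop("code array size mismatch");
  NumericMatrix out(2, nsnp);
  for (int j = 0; j < nsnp; ++j) {
    R_xlen_t off = (R_xlen_t)j * bps;
    double s = 0; int nobs = 0;
    for (int k = 0; k < ng; ++k) {
      int code = (codes[off + k / 4] >> (2 * (k % 4))) & 3;
      if (code != 1) { s += (code == 0 ? 0 : code - 1); ++nobs; }
    }
    out(0, j) = s;
    out(1, j) = nobs;
  }
  return out;
}

// Y = Z V with Z the implicitly centered genotype matrix (n_g x n_snp),
// V an n_snp x k panel. The packed store is streamed in SNP blocks; each
// block is decoded into a small dense panel and accumulated, so the working
// set stays cache-sized.
// [[Rcpp::export]]
NumericMatrix plink_z_matmat_cpp(RawVector codes, int ng, int nsnp,
                                 NumericVector p, NumericMatrix v,
                                 int block_snps) {
  const int bps = (ng + 3) / 4;
  const int k = v.ncol();
  if (v.nrow() != nsnp) stop("Z matmat: V must have n_snp rows");
  if (p.size() != nsnp) stop("Z matmat: frequency vector length mismatch");
  if (block_snps < 1) block_snps = 32;
  NumericMatrix y(ng, k);
  std::vector<double> panel; // decoded centered block, ng x nb, col-major
  for (int j0 = 0; j0 < nsnp; j0 += block_snps) {
    const int nb = std::min(block_snps, nsnp - j0);
    panel.assign((size_t)ng * nb, 0.0);
    for (int jb = 0; jb < nb; ++jb) {
      const int j = j0 + jb;
      const double twop = 2.0 * p[j];
      R_xlen_t off = (R_xlen_t)j * bps;
      double *col = &panel[(size_t)jb * ng];
      for (int kk = 0; kk < ng; ++kk) {
        int code = (codes[off + kk / 4] >> (2 * (kk % 4))) & 3;
        col[kk] = code_value(code, twop);
      }
    }
    for (int c = 0; c < k; ++c) {
      for (int jb = 0; jb < nb; ++jb) {
        const double vj = v(j0 + jb, c);
        if (vj == 0.0) continue;
        const double *col = &panel[(size_t)jb * ng];
        for (int kk = 0; kk < ng; ++kk) y(kk, c) += col[kk] * vj;
      }
    }
  }
  return y;
}

// Y = Z' V, V an n_g x k panel; transpose analogue of plink_z_matmat_cpp.
// [[Rcpp::export]]
NumericMatrix plink_zt_matmat_cpp(RawVector codes, int ng, int nsnp,
                                  NumericVector p, NumericMatrix v,
                                  int block_snps) {
  const int bps = (ng + 3) / 4;
  const int k = v.ncol();
  if (v.nrow() != ng) stop("Z' matmat: V must have n_g rows");
  if (p.size() != nsnp) stop("Z' matmat: frequency vector length mismatch");
  if (block_snps < 1) block_snps = 32;
  NumericMatrix y(nsnp, k);
  std::vector<double> panel;
  for (int j0 = 0; j0 < nsnp; j0 += block_snps) {
    const int nb = std::min(block_snps, nsnp - j0);
    panel.assign((size_t)ng * nb, 0.0);
    for (int jb = 0; jb < nb; ++jb) {
      const int j = j0 + jb;
      const double twop = 2.0 * p[j];
      R_xlen_t off = (R_xlen_t)j * bps;
      double *col = &panel[(size_t)jb * ng];
      for (int kk = 0; kk < ng; ++kk) {
        int code = (codes[off + kk / 4] >> (2 * (kk % 4))) & 3;
        col[kk] = code_value(code, twop);
      }
    }
    for (int c = 0; c < k; ++c) {
      for (int jb = 0; jb < nb; ++jb) {
        const double *col = &panel[(size_t)jb * ng];
        double acc = 0.0;
        for (int kk = 0; kk < ng; ++kk) acc += col[kk] * v(kk, c);
        y(j0 + jb, c) = acc;
      }
    }
  }
  return y;
}

// Centered dense panel for SNP columns [snp_from, snp_to] (1-based,
// inclusive); missing -> 0. Used by the blocked exact pass computing
// per-SNP data-part diagonal blocks of the preconditioner.
// [[Rcpp::export]]
NumericMatrix plink_decode_centered_cpp(RawVector codes, int ng, int nsnp,
                                        NumericVector p, int snp_from,
                                        int snp_to) {
  const int bps = (ng + 3) / 4;
  if (snp_from < 1 || snp_to > nsnp || snp_from > snp_to)
    stop("invalid SNP range");
  const int nb = snp_to - snp_from + 1;
  NumericMatrix out(ng, nb);
  for (int jb = 0; jb < nb; ++jb) {
    const int j = snp_from - 1 + jb;
    const double twop = 2.0 * p[j];
    R_xlen_t off = (R_xlen_t)j * bps;
    for (int kk = 0; kk < ng; ++kk) {
      int code = (codes[off + kk / 4] >> (2 * (kk % 4))) & 3;
      out(kk, jb) = code_value(code, twop);
    }
  }
  return out;
}
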