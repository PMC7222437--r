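#' Bit-packed genotype store (PLINK 1 layout, SNP-major)
#'
#' Genotypes are held in memory exactly as in a PLINK 1 `.bed` file:
#' 2 bits per call, four animals per byte, `ceiling(n_g / 4)` bytes per
#' SNP, SNP-major. Code map: `0b00` = 0 copies of the counted allele,
#' `0b01` = missing, `0b10` = 1 copy, `0b11` = 2 copies. The centered
#' genotype matrix Z is never materialised: [z_matmat()] and
#' [zt_matmat()] decode cache-sized blocks on the fly. A dense
#' double-precision copy would need 32 times the memory of the packed
#' store (see [packed_footprint_bytes()]).
#'
#' @param codes Raw vector of packed codes (`ceiling(n_g/4) * n_snp`).
#' @param n_g,n_snp Numbers of genotyped animals and SNPs.
#' @param animal_ids,snp_ids Label vectors.
#' @param alleles Optional 2-column matrix of allele labels (A1, A2); the
#'   counted allele is A2, the second allele of each `.bim` record.
#' @return An object of class `packed_genotypes`.
#' @export
packed_genotypes <- function(codes, n_g, n_snp,
                             animal_ids = as.character(seq_len(n_g)),
                             snp_ids = paste0("snp", seq_len(n_snp)),
                             alleles = NULL) {
  n_g <- as.integer(n_g); n_snp <- as.integer(n_snp)
  bps <- (n_g + 3L) %/% 4L
  if (!is.raw(codes) || length(codes) != bps * n_snp)
    stop("codes must be a raw vector of ceiling(n_g/4) * n_snp bytes")
  stopifnot(length(animal_ids) == n_g, length(snp_ids) == n_snp)
  structure(list(codes = codes, n_g = n_g, n_snp = n_snp,
                 animal_ids = as.character(animal_ids),
                 snp_ids = as.character(snp_ids), alleles = alleles),
            class = "packed_genotypes")
}

#' @export
print.packed_genotypes <- function(x, ...) {
  fp <- packed_footprint_bytes(x$n_g, x$n_snp)
  cat(sprintf("Packed genotypes: %d animals x %d SNPs, %s bytes packed (dense double: %s bytes)\n",
              x$n_g, x$n_snp, format(fp$packed, big.mark = ","),
              format(fp$dense_double, big.mark = ",")))
  invisible(x)
}

#' Pack an integer dosage matrix
#'
#' @param dosages Integer matrix, animals x SNPs; values 0/1/2, `NA` =
#'   missing.
#' @inheritParams packed_genotypes
#' @return A [packed_genotypes] object.
#' @export
pack_genotypes <- function(dosages,
                           animal_ids = rownames(dosages) %||%
                             as.character(seq_len(nrow(dosages))),
                           snp_ids = colnames(dosages) %||%
                             paste0("snp", seq_len(ncol(dosages)))) {
  m <- as.matrix(dosages)
  storage.mode(m) <- "integer"
  packed_genotypes(plink_pack_cpp(m), nrow(m), ncol(m),
                   animal_ids = animal_ids, snp_ids = snp_ids)
}

#' Decode to an integer dosage matrix (NA = missing)
#' @param pg A [packed_genotypes] object.
#' @export
unpack_genotypes <- function(pg) {
  out <- plink_unpack_cpp(pg$codes, pg$n_g, pg$n_snp)
  dimnames(out) <- list(pg$animal_ids, pg$snp_ids)
  out
}

#' Read a PLINK 1 binary fileset
#'
#' Only the SNP-major dialect (mode byte `0x01`) is supported; the
#' individual-major dialect is rejected, not converted. The packed bytes
#' are stored verbatim (no decode). `.fam`/`.bim` are parsed for ids and
#' alleles only; the counted allele is the second allele (A2) of each
#' `.bim` record.
#'
#' @param bed_path,bim_path,fam_path File paths; `bim_path`/`fam_path`
#'   default to `bed_path` with swapped extensions.
#' @return A [packed_genotypes] object.
#' @export
read_bed <- function(bed_path,
                     bim_path = sub("\\.bed$", ".bim", bed_path),
                     fam_path = sub("\\.bed$", ".fam", bed_path)) {
  fam <- utils::read.table(fam_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(bim_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  n_g <- nrow(fam); n_snp <- nrow(bim)
  bps <- (n_g + 3L) %/% 4L
  expected <- 3 + bps * n_snp
  sz <- file.info(bed_path)$size
  raw_all <- readBin(bed_path, "raw", n = expected + 1L)
  if (length(raw_all) < 3L ||
      raw_all[1L] != as.raw(0x6c) || raw_all[2L] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes): ", bed_path)
  if (raw_all[3L] == as.raw(0x00))
    stop("individual-major .bed files (mode 0x00) are not supported")
  if (raw_all[3L] != as.raw(0x01))
    stop("unknown .bed mode byte: ", as.integer(raw_all[3L]))
  if (sz != expected)
    stop(sprintf(".bed size mismatch: %d bytes found, %d expected for %d animals x %d SNPs",
                 sz, expected, n_g, n_snp))
  packed_genotypes(raw_all[-(1:3)], n_g, n_snp,
                   animal_ids = fam[[2L]], snp_ids = bim[[2L]],
                   alleles = cbind(A1 = bim[[5L]], A2 = bim[[6L]]))
}

#' Write a PLINK 1 binary fileset
#'
#' @param pg A [packed_genotypes] object.
#' @param prefix Output path prefix (`prefix.bed/.bim/.fam` are written).
#' @return Invisibly, the three paths.
#' @export
write_bed <- function(pg, prefix) {
  bed <- paste0(prefix, ".bed")
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(pg$codes, con)
  close(con)
  al <- pg$alleles %||% cbind(rep("A", pg$n_snp), rep("B", pg$n_snp))
  bim <- data.frame(chr = 1L, id = pg$snp_ids, cm = 0,
                    pos = seq_len(pg$n_snp), a1 = al[, 1L], a2 = al[, 2L])
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = pg$animal_ids, iid = pg$animal_ids,
                    father = 0L, mother = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(c(bed, paste0(prefix, ".bim"), paste0(prefix, ".fam")))
}

#' Observed allele frequencies and the scaling constant m
#'
#' `p_j` = (sum of non-missing counted-allele dosages) / (2 x non-missing
#' calls); missing calls are excluded from the estimate. `m = 2 sum_j
#' p_j (1 - p_j)` links the per-SNP effect variance to the additive
#' genetic variance and uses the same `p` as the centering.
#'
#' @param pg A [packed_genotypes] object.
#' @param on_all_missing `"error"` (default) or `"warn"`; with `"warn"`,
#'   SNPs with no non-missing call get `p = 0` (a zero column of Z) and a
#'   warning names them.
#' @return List of class `centering_info`: `p`, `m`, `n_obs`.
#' @export
allele_frequencies <- function(pg, on_all_missing = c("error", "warn")) {
  on_all_missing <- match.arg(on_all_missing)
  cnt <- plink_counts_cpp(pg$codes, pg$n_g, pg$n_snp)
  nobs <- cnt[2L, ]
  if (any(nobs == 0)) {
    bad <- pg$snp_ids[nobs == 0]
    msg <- paste0("SNP(s) with all calls missing: ",
                  paste(utils::head(bad, 5), collapse = ", "))
    if (on_all_missing == "error") stop(msg) else warning(msg)
  }
  p <- ifelse(nobs > 0, cnt[1L, ] / (2 * pmax(nobs, 1)), 0)
  structure(list(p = p, m = 2 * sum(p * (1 - p)), n_obs = nobs),
            class = "centering_info")
}

#' Centered genotype products Z V and Z' V
#'
#' `Z[k, j] = dosage - 2 p_j` for non-missing calls and `0` for missing
#' ones (mean imputation). The packed store is decoded block by block into
#' small dense panels that are multiplied and accumulated, never as a full
#' dense matrix.
#'
#' @param pg A [packed_genotypes] object.
#' @param cinfo [allele_frequencies()] output (or any list with `p`).
#' @param v Numeric vector/matrix: `n_snp` rows for [z_matmat()], `n_g`
#'   rows for [zt_matmat()].
#' @param block_snps SNPs per decoded panel (default 32).
#' @return Dense product, `n_g` (or `n_snp`) rows.
#' @export
z_matmat <- function(pg, cinfo, v, block_snps = 32L) {
  was_vec <- is.null(dim(v))
  vm <- as_col_matrix(v, pg$n_snp)
  y <- plink_z_matmat_cpp(pg$codes, pg$n_g, pg$n_snp, cinfo$p, vm,
                          as.integer(block_snps))
  if (was_vec) drop(y) else y
}

#' @rdname z_matmat
#' @export
zt_matmat <- function(pg, cinfo, v, block_snps = 32L) {
  was_vec <- is.null(dim(v))
  vm <- as_col_matrix(v, pg$n_g)
  y <- plink_zt_matmat_cpp(pg$codes, pg$n_g, pg$n_snp, cinfo$p, vm,
                           as.integer(block_snps))
  if (was_vec) drop(y) else y
}

# Dense centered Z (small stores only: tests, exact preconditioners).
z_dense <- function(pg, cinfo) {
  plink_decode_centered_cpp(pg$codes, pg$n_g, pg$n_snp, cinfo$p,
                            1L, pg$n_snp)
}

#' Memory accounting for packed vs dense genotype storage
#'
#' Packed: `ceiling(n_g / 4)` bytes per SNP. Dense double: `8 n_g n_snp`
#' bytes. Frequency array: `8 n_snp` bytes. The dense/packed ratio is 32
#' (ignoring the frequency array).
#'
#' @param n_g,n_snp Positive counts.
#' @return List `packed`, `dense_double`, `freq_array` (bytes, numeric).
#' @export
packed_footprint_bytes <- function(n_g, n_snp) {
  stopifnot(n_g > 0, n_snp > 0)
  list(packed = ceiling(n_g / 4) * n_snp,
       dense_double = 8 * n_g * n_snp,
       freq_array = 8 * n_snp)
}

#' Reorder the animals of a packed store
#'
#' Used to align a genotype file with the pedigree's genotyped-animal
#' order. Repacks via a decode, so intended for desk-scale stores.
#'
#' @param pg A [packed_genotypes] object.
#' @param perm Integer permutation of `1:n_g` (new order).
#' @return A [packed_genotypes] object.
#' @export
reorder_genotypes <- function(pg, perm) {
  stopifnot(length(perm) == pg$n_g, !anyDuplicated(perm))
  d <- unpack_genotypes(pg)[perm, , drop = FALSE]
  out <- pack_genotypes(d, animal_ids = pg$animal_ids[perm],
                        snp_ids = pg$snp_ids)
  out$alleles <- pg$alleles
  out
}
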