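#' @useDynLib ssnpblup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Symmetric sparse matrix in three-array compressed row storage (CRS3)
#'
#' Stores the upper triangle (column index \eqn{j \ge i}) of a symmetric
#' sparse matrix in the classical three-array compressed row form: integer
#' row pointers `IA` (length `n_rows + 1`), integer column indices `JA`
#' (sorted within each row) and real values `AA`. The symmetric
#' matrix-vector product applies every off-diagonal entry twice.
#'
#' This is the in-memory carrier for the sparse inverse numerator
#' relationship matrix \eqn{A^{-1}} and its derived operators, chosen for
#' its predictable footprint: with 4-byte integers and 8-byte reals, a
#' matrix with `nnz` stored entries occupies `4 * (n_rows + 1) + 12 * nnz`
#' bytes (see [crs3_bytes()]).
#'
#' @param ia Integer row-pointer array, 1-based, length `n_rows + 1`.
#' @param ja Integer column indices of stored entries.
#' @param aa Numeric values of stored entries.
#' @param n_rows Matrix order.
#' @return An object of class `crs3`.
#' @seealso [crs3_from_triplets()], [crs3_matmat()], [crs3_bytes()]
#' @export
crs3 <- function(ia, ja, aa, n_rows) {
  ia <- as.integer(ia); ja <- as.integer(ja)
  aa <- as.numeric(aa); n_rows <- as.integer(n_rows)
  x <- structure(list(n_rows = n_rows, ia = ia, ja = ja, aa = aa),
                 class = "crs3")
  crs3_validate(x)
  x
}

crs3_validate <- function(x) {
  stopifnot(inherits(x, "crs3"))
  n <- x$n_rows
  if (length(x$ia) != n + 1L) stop("IA must have length n_rows + 1")
  if (x$ia[1L] != 1L) stop("IA must start at 1")
  if (any(diff(x$ia) < 0L)) stop("IA must be non-decreasing")
  nnz <- x$ia[n + 1L] - 1L
  if (length(x$ja) != nnz || length(x$aa) != nnz)
    stop("JA/AA length must match IA[n_rows + 1] - 1")
  if (nnz > 0L) {
    row <- rep.int(seq_len(n), diff(x$ia))
    if (any(x$ja < row)) stop("only the upper triangle (j >= i) may be stored")
    if (any(x$ja > n)) stop("column index out of range")
    d <- diff(x$ja)
    same_row <- diff(row) == 0L
    if (any(d[same_row] <= 0L))
      stop("JA must be strictly increasing within each row")
  }
  invisible(x)
}

#' Build a CRS3 matrix from (possibly duplicated) symmetric triplets
#'
#' Entries are normalised to the upper triangle (i, j swapped where needed)
#' and duplicates are summed, which is exactly how per-animal contributions
#' to \eqn{A^{-1}} accumulate.
#'
#' @param i,j Integer indices (1-based) of contributions.
#' @param x Numeric contribution values.
#' @param n Matrix order.
#' @param drop_zero Drop entries that cancel to exactly zero.
#' @return A [crs3] object.
#' @export
crs3_from_triplets <- function(i, j, x, n, drop_zero = FALSE) {
  ii <- pmin(i, j); jj <- pmax(i, j)
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = c(n, n))
  if (drop_zero) m <- Matrix::drop0(m)
  crs3_from_sparse(m)
}

# from any Matrix sparse (upper-triangular content assumed) to crs3
crs3_from_sparse <- function(m) {
  r <- as(as(m, "generalMatrix"), "RsparseMatrix")
  crs3(ia = r@p + 1L, ja = r@j + 1L, aa = r@x, n_rows = nrow(m))
}

#' Number of stored non-zeros of a CRS3 matrix
#' @param x A [crs3] object.
#' @export
crs3_nnz <- function(x) x$ia[x$n_rows + 1L] - 1L

#' Symmetric matrix product `S %*% V` for a CRS3 matrix
#'
#' @param x A [crs3] object.
#' @param v Numeric vector or matrix with `n_rows` rows.
#' @return Numeric matrix (or vector when `v` is a vector).
#' @export
crs3_matmat <- function(x, v) {
  was_vec <- is.null(dim(v))
  vm <- if (was_vec) matrix(as.numeric(v), ncol = 1L) else
    as.matrix(v) * 1.0
  y <- crs3_sym_matmat_cpp(x$ia, x$ja, x$aa, vm)
  if (was_vec) drop(y) else y
}

#' Diagonal of a CRS3 matrix
#' @param x A [crs3] object.
#' @export
crs3_diag <- function(x) {
  d <- numeric(x$n_rows)
  row <- rep.int(seq_len(x$n_rows), diff(x$ia))
  on_diag <- x$ja == row
  d[row[on_diag]] <- x$aa[on_diag]
  d
}

# dsCMatrix view (upper storage), for factorization and block extraction
crs3_to_dsc <- function(x) {
  row <- rep.int(seq_len(x$n_rows), diff(x$ia))
  Matrix::sparseMatrix(i = row, j = x$ja, x = x$aa,
                       dims = c(x$n_rows, x$n_rows), symmetric = TRUE)
}

# dense symmetric matrix (small n only; tests and diagnostics)
crs3_to_dense <- function(x) {
  as.matrix(as(crs3_to_dsc(x), "generalMatrix"))
}

#' Storage accounting for a CRS3 matrix
#'
#' Bytes needed by the three arrays with `int_bytes`-byte integers and
#' `real_bytes`-byte reals: `int_bytes * (n_rows + 1)` for `IA`,
#' `int_bytes * nnz` for `JA` and `real_bytes * nnz` for `AA`.
#'
#' @param n_rows Matrix order.
#' @param nnz Number of stored non-zeros.
#' @param int_bytes,real_bytes Element sizes in bytes.
#' @return Total bytes (numeric, exact).
#' @seealso [crs3_ainv_bound_bytes()] for the pedigree-specific upper bound.
#' @export
crs3_bytes <- function(n_rows, nnz, int_bytes = 4, real_bytes = 8) {
  int_bytes * (n_rows + 1) + (int_bytes + real_bytes) * nnz
}

#' Upper bound on CRS3 bytes for a pedigree inverse relationship matrix
#'
#' Henderson's rules add at most one diagonal and three off-diagonal
#' upper-triangle entries per animal, so the upper triangle of
#' \eqn{A^{-1}} for `n` animals holds at most `4n` non-zeros and its CRS3
#' form at most `4(n+1) + 4*4n + 8*4n = 52n + 4` bytes.
#'
#' @param n Number of animals in the pedigree.
#' @return Bytes (numeric, exact; `52 * n + 4`).
#' @export
crs3_ainv_bound_bytes <- function(n) 52 * n + 4

#' @export
print.crs3 <- function(x, ...) {
  cat(sprintf("CRS3 symmetric sparse matrix: %d x %d, %d stored non-zeros (upper triangle)\n",
              x$n_rows, x$n_rows, crs3_nnz(x)))
  cat(sprintf("  storage: %s bytes (4-byte ints, 8-byte reals)\n",
              format(crs3_bytes(x$n_rows, crs3_nnz(x)), big.mark = ",")))
  invisible(x)
}
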