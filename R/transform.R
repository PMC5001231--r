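#' Center each row at zero
#'
#' Subtracts from every row its mean, removing per-gene background signal.
#' This is the first of the two transforms applied before the centralized
#' concordance index is computed.
#'
#' @param x Numeric matrix (genes in rows).
#' @return Matrix of the same shape; every row has mean zero.
#' @seealso [standardize_rows()], [cci()]
#' @examples
#' centralize_rows(rbind(c(1, 2, 3), c(5, 5, 5)))
#' @export
centralize_rows <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(!is.finite(x))) stop("x contains non-finite values")
  x - rowMeans(x)
}

#' Scale each row to unit Euclidean norm
#'
#' The second transform: after centering, each row is divided by its norm so
#' that every gene contributes equally regardless of expression magnitude.
#' Rows of the result are unit vectors whose pairwise inner products are the
#' Pearson correlations of the original genes.
#'
#' @param x Numeric matrix with centered rows (any matrix with no zero rows
#'   is accepted; centering is not re-checked).
#' @return Matrix of the same shape with unit-norm rows.
#' @examples
#' standardize_rows(centralize_rows(rbind(c(1, 2, 3), c(2, 0, 1))))
#' @export
standardize_rows <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    bad <- which(norms == 0)
    ids <- if (is.null(rownames(x))) paste0("row ", bad) else rownames(x)[bad]
    stop("zero-norm (constant) rows cannot be standardized: ",
         paste(ids, collapse = ", "))
  }
  x / norms
}

#' Pairwise Pearson correlation between rows
#'
#' Computed as the Gram matrix of the centered, row-standardized matrix,
#' which equals the gene-gene Pearson correlation matrix. The leading
#' eigenvalue of this matrix, divided by the number of genes, is the CCI.
#'
#' @param x Numeric matrix, n genes (rows, n >= 2) by N samples (N >= 3),
#'   no constant rows.
#' @return Symmetric n-by-n matrix with unit diagonal, entries in \[-1, 1\].
#' @export
row_pearson_matrix <- function(x) {
  validate_expression_matrix(x)
  x <- handle_constant_rows(x, "error", caller = "row_pearson_matrix")
  gh <- standardize_rows(centralize_rows(x))
  r <- tcrossprod(gh)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Numerical rank of a matrix
#'
#' Counts singular values above a scale-aware tolerance,
#' `max(dim(x)) * eps * s_max` by default — the standard numerical-rank
#' convention. For a noiseless matrix whose rows are affine transforms of one
#' base profile the raw rank is 2, and the rank after row centering and
#' standardization is 1.
#'
#' @param x Numeric matrix with finite entries.
#' @param tol Tolerance below which a singular value counts as zero; `NULL`
#'   (default) uses `max(dim(x)) * .Machine$double.eps * max(singular value)`.
#' @return Integer rank estimate.
#' @examples
#' numerical_rank(outer(1:4, 1:5))  # 1
#' @export
numerical_rank <- function(x, tol = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(!is.finite(x))) stop("x contains non-finite values")
  d <- svd(x, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(x)) * .Machine$double.eps * d[1]
  sum(d > tol)
}
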