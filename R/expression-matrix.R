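#' Validate a genes-by-samples expression matrix
#'
#' Checks the structural invariants every concordance computation relies on:
#' a numeric matrix with finite entries, at least `min_genes` rows (genes) and
#' `min_samples` columns (samples), and unique row/column identifiers when
#' dimnames are present.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @param min_genes Minimum number of rows required (default 2).
#' @param min_samples Minimum number of columns required (default 3).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' validate_expression_matrix(m)
#' @export
validate_expression_matrix <- function(x, min_genes = 2L, min_samples = 3L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes in rows, samples in columns)")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains non-finite values (NA/NaN/Inf)")
  if (nrow(x) < min_genes)
    stop(sprintf("need at least %d genes (rows), got %d", min_genes, nrow(x)))
  if (ncol(x) < min_samples)
    stop(sprintf("need at least %d samples (columns), got %d", min_samples, ncol(x)))
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  invisible(x)
}

#' Find constant (zero-variance) rows
#'
#' A constant gene has zero residual after row-centering, so it cannot be
#' standardized to unit norm; all concordance statistics treat such rows as
#' degenerate.
#'
#' @param x Numeric matrix.
#' @return Integer vector of row indices whose entries are all equal.
#' @export
constant_rows <- function(x) {
  which(rowSums((x - rowMeans(x))^2) == 0)
}

# Shared degenerate-row guard: error (naming the genes) or drop with warning.
handle_constant_rows <- function(x, on_constant = c("error", "drop"), caller = "cci") {
  on_constant <- match.arg(on_constant)
  bad <- constant_rows(x)
  if (length(bad) == 0L) return(x)
  ids <- if (is.null(rownames(x))) paste0("row ", bad) else rownames(x)[bad]
  if (on_constant == "error")
    stop(caller, ": constant (zero-variance) rows cannot be standardized: ",
         paste(ids, collapse = ", "))
  warning(caller, ": dropping ", length(bad), " constant row(s): ",
          paste(ids, collapse = ", "))
  x[-bad, , drop = FALSE]
}
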