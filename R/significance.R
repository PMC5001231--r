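#' Permute the entries of every row independently
#'
#' Destroys all gene-gene correlation structure while preserving each gene's
#' marginal value multiset — the within-row permutation null for the CCI.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape; each row a fresh uniform permutation of
#'   the corresponding input row.
#' @export
permute_within_rows <- function(x) {
  if (!is.matrix(x)) stop("x must be a matrix")
  N <- ncol(x)
  out <- x
  for (i in seq_len(nrow(x))) out[i, ] <- x[i, sample.int(N)]
  out
}

# Constructor for a resampled null distribution summary.
new_null_distribution <- function(kind, values, seed = NULL) {
  structure(
    list(kind = kind, values = values, M = length(values),
         mean = mean(values), sd = stats::sd(values), seed = seed),
    class = "cci_null")
}

#' @export
print.cci_null <- function(x, ...) {
  cat(sprintf("CCI null distribution (%s), M = %d\n", x$kind, x$M))
  cat(sprintf("  mean %.6g, sd %.6g\n", x$mean, x$sd))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Permutation p-value for a module's CCI
#'
#' Recomputes the CCI on M copies of the module matrix with every row
#' independently permuted, and reports the fraction of permuted statistics
#' at least as large as the observed one: `p = #(CCI_p >= CCI) / M`, with no
#' pseudocount, so p = 0 is possible and means "below the resolution 1/M".
#'
#' Permutation is applied to the raw rows; since centering and
#' standardization commute with any fixed column reordering applied per row,
#' this equals permuting the transformed rows.
#'
#' @param x Module expression matrix (n >= 2 genes, N >= 3 samples).
#' @param M Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `p_permute`, `observed_cci`, `min_resolvable_p` (= 1/M),
#'   and `null` (a `"cci_null"` holding the M permuted CCIs).
#' @export
permutation_pvalue <- function(x, M = 1000L, seed = NULL) {
  if (M < 1) stop("M must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  validate_expression_matrix(x)
  x <- handle_constant_rows(x, "error", caller = "permutation_pvalue")
  observed <- .cci_stat(x)
  vals <- vapply(seq_len(M), function(i) .cci_stat(permute_within_rows(x)),
                 numeric(1))
  list(p_permute = mean(vals >= observed),
       observed_cci = observed,
       min_resolvable_p = 1 / M,
       null = new_null_distribution("permutation", vals, seed))
}

#' Random gene-set null distribution of the CCI
#'
#' Draws M gene sets of size n uniformly without replacement from a
#' genome-wide expression matrix and records each set's CCI. The resulting
#' distribution is the reference against which an observed module CCI is
#' standardized into a z-score; empirically it is bell-shaped, which is what
#' justifies the normal-tail p-value.
#'
#' Genes that are constant across samples are excluded from the sampling
#' frame (with a message); random sets may overlap the module under test.
#'
#' @param genome Genes-by-samples expression matrix for the whole dataset.
#' @param n Module size to match.
#' @param M Number of random gene sets (default 1000, >= 2).
#' @param seed Optional integer seed.
#' @return A `"cci_null"` object (kind `"random_geneset"`).
#' @export
sample_random_module_null <- function(genome, n, M = 1000L, seed = NULL) {
  if (M < 2) stop("M must be >= 2 for a random gene-set null")
  if (!is.null(seed)) set.seed(seed)
  validate_expression_matrix(genome)
  bad <- constant_rows(genome)
  if (length(bad) > 0L) {
    message("excluding ", length(bad), " constant gene(s) from the sampling frame")
    genome <- genome[-bad, , drop = FALSE]
  }
  if (n < 2 || n > nrow(genome))
    stop(sprintf("cannot sample %d genes from %d usable genes", n, nrow(genome)))
  vals <- vapply(seq_len(M), function(i) {
    .cci_stat(genome[sample.int(nrow(genome), n), , drop = FALSE])
  }, numeric(1))
  new_null_distribution("random_geneset", vals, seed)
}

#' Standardize an observed CCI against a resampled null
#'
#' `z = (observed - mean(null)) / sd(null)`, with the one-tail p-value from
#' the standard normal upper tail. The z-score is preferred over the
#' empirical percentile because M resamples cannot resolve very small
#' p-values, and z-scores from different conditions share a scale and can be
#' compared directly.
#'
#' @param observed_cci Observed module CCI.
#' @param null A `"cci_null"` (or any list with `mean` and `sd`).
#' @return List with `observed_cci`, `z`, `p_one_tail`, `null`.
#' @examples
#' cci_zscore(0.5, list(mean = 0.2, sd = 0.01))$z  # 30
#' @export
cci_zscore <- function(observed_cci, null) {
  if (is.null(null$sd) || is.na(null$sd) ||
      null$sd <= 1e-12 * max(1, abs(null$mean)))
    stop("null distribution has zero or undefined spread; z-score undefined")
  z <- (observed_cci - null$mean) / null$sd
  list(observed_cci = observed_cci, z = z,
       p_one_tail = stats::pnorm(z, lower.tail = FALSE), null = null)
}

#' Bonferroni-adjusted one-tail z threshold
#'
#' The standard-normal upper-tail quantile at `alpha / m_tests`: a module is
#' called significantly concordant when its z-score meets or exceeds this
#' threshold, controlling family-wise error over m tested modules.
#'
#' @param alpha Family-wise one-tail significance level in (0, 1).
#' @param m_tests Number of modules tested (>= 1).
#' @return The threshold tau.
#' @examples
#' bonferroni_z_threshold(0.05, 168)  # 3.4338
#' @export
bonferroni_z_threshold <- function(alpha, m_tests = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (!is.numeric(m_tests) || length(m_tests) != 1L || m_tests < 1)
    stop("m_tests must be a single integer >= 1")
  stats::qnorm(alpha / m_tests, lower.tail = FALSE)
}
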