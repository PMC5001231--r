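#' Resolve a gene module against an expression matrix
#'
#' Genes absent from the matrix are dropped with a warning; if fewer than
#' two genes survive, resolution fails. Platform/gene-list mismatches are
#' routine, so missing genes are not an error, but the reduced size is
#' always reported so downstream records carry `n_used`, not the nominal
#' module size.
#'
#' @param genes Character vector of gene identifiers (no duplicates).
#' @param expr Expression matrix with gene identifiers as rownames.
#' @return Character vector of the identifiers present in `expr`.
#' @export
resolve_module <- function(genes, expr) {
  if (anyDuplicated(genes))
    stop("module contains duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (is.null(rownames(expr)))
    stop("expression matrix has no gene identifiers (rownames)")
  hit <- genes %in% rownames(expr)
  if (!all(hit))
    warning(sum(!hit), " of ", length(genes),
            " module gene(s) absent from the expression matrix; dropped")
  found <- genes[hit]
  if (length(found) < 2L)
    stop("fewer than 2 module genes found in the expression matrix")
  found
}

#' Score one module in one condition
#'
#' Computes the module's CCI on the condition's expression matrix and its
#' z-score against a size-matched random gene-set null drawn from the same
#' matrix.
#'
#' @param genes Character vector of module gene identifiers.
#' @param expr Genes-by-samples expression matrix for the condition.
#' @param M Null resamples (default 1000).
#' @param seed Optional integer seed (used for the null draw).
#' @param null Optional precomputed `"cci_null"` of matching size, e.g. a
#'   cached null shared between same-size modules; when supplied, `M` and
#'   `seed` are ignored.
#' @return List with `cci` (full `"cci_result"`), `z`, `p_one_tail`,
#'   `n_used`, and `null`.
#' @export
score_module_in_condition <- function(genes, expr, M = 1000L, seed = NULL,
                                      null = NULL) {
  found <- resolve_module(genes, expr)
  res <- cci(expr[found, , drop = FALSE], on_constant = "drop")
  if (is.null(null))
    null <- sample_random_module_null(expr, res$n, M = M, seed = seed)
  zs <- cci_zscore(res$cci, null)
  list(cci = res, z = zs$z, p_one_tail = zs$p_one_tail,
       n_used = res$n, null = null)
}

# Deterministic per-(seed, module-size) sub-seed, kept inside 32-bit range.
# Depending only on the size (not the condition) makes screening exactly
# symmetric under swapping the two condition matrices.
.size_seed <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1009 * n) %% (2^31 - 1))
}

#' Screen modules for condition-specific co-expression
#'
#' Scores every module in both conditions (each against a random gene-set
#' null drawn from that condition's own matrix) and classifies each module
#' by comparing both z-scores to the Bonferroni-adjusted threshold
#' `tau = bonferroni_z_threshold(alpha, length(modules))`. A module is
#' called significant in a condition when `z >= tau`; verdicts are
#' `specific_to_a` (significant in A only), `specific_to_b`,
#' `concordant_both`, or `concordant_neither`.
#'
#' Nulls are cached per (condition, module size): two same-size modules in
#' the same condition share one null, which is statistically identical and
#' M-fold cheaper. A module that cannot be resolved in a condition (fewer
#' than two genes present) gets `NA` scores there and is classified from
#' the available side only as `concordant_neither`, with a warning.
#'
#' @param modules Named list of character vectors (gene identifiers), e.g.
#'   from [read_gene_sets()].
#' @param expr_a,expr_b Genes-by-samples matrices for the two conditions.
#' @param alpha Family-wise one-tail level (default 0.05).
#' @param M Null resamples per (condition, size) (default 1000).
#' @param seed Optional integer seed; makes the whole screen deterministic.
#' @return Data frame with one row per module: `module`, `n_used_a`,
#'   `n_used_b`, `cci_a`, `cci_b`, `z_a`, `z_b`, `tau`, `verdict`.
#'   `tau` and the per-size null cache keys are attached as attributes
#'   `tau` and `null_cache_keys`.
#' @examples
#' set.seed(1)
#' bg <- matrix(runif(200 * 12), 200, 12,
#'              dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
#' exa <- bg; exa[1:8, ] <- make_correlated_matrix(8, 12)
#' mods <- list(planted = paste0("g", 1:8), random = paste0("g", 101:108))
#' screen_modules(mods, exa, bg, M = 50, seed = 1)
#' @export
screen_modules <- function(modules, expr_a, expr_b, alpha = 0.05,
                           M = 1000L, seed = NULL) {
  if (length(modules) == 0L) stop("empty module list")
  if (is.null(names(modules)) || any(!nzchar(names(modules))))
    names(modules) <- paste0("module_", seq_along(modules))
  tau <- bonferroni_z_threshold(alpha, length(modules))

  cache_a <- new.env(parent = emptyenv())
  cache_b <- new.env(parent = emptyenv())
  score_one <- function(genes, expr, cache) {
    found <- tryCatch(suppressWarnings(resolve_module(genes, expr)),
                      error = function(e) NULL)
    if (is.null(found)) return(list(n = NA_integer_, cci = NA_real_, z = NA_real_))
    res <- cci(expr[found, , drop = FALSE], on_constant = "drop")
    key <- as.character(res$n)
    if (is.null(cache[[key]]))
      cache[[key]] <- sample_random_module_null(expr, res$n, M = M,
                                                seed = .size_seed(seed, res$n))
    list(n = res$n, cci = res$cci, z = cci_zscore(res$cci, cache[[key]])$z)
  }

  rec <- lapply(seq_along(modules), function(i) {
    a <- score_one(modules[[i]], expr_a, cache_a)
    b <- score_one(modules[[i]], expr_b, cache_b)
    if (is.na(a$z) || is.na(b$z))
      warning("module '", names(modules)[i],
              "' unresolvable in at least one condition; verdict set to concordant_neither")
    sig_a <- !is.na(a$z) && a$z >= tau
    sig_b <- !is.na(b$z) && b$z >= tau
    verdict <- if (sig_a && sig_b) "concordant_both"
      else if (sig_a) "specific_to_a"
      else if (sig_b) "specific_to_b"
      else "concordant_neither"
    data.frame(module = names(modules)[i],
               n_used_a = a$n, n_used_b = b$n,
               cci_a = a$cci, cci_b = b$cci,
               z_a = a$z, z_b = b$z,
               tau = tau, verdict = verdict)
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  attr(out, "tau") <- tau
  attr(out, "null_cache_keys") <- list(a = ls(cache_a), b = ls(cache_b))
  attr(out, "seed") <- seed
  out
}

#' Split one expression matrix into two condition matrices
#'
#' @param expr Genes-by-samples matrix.
#' @param groups Factor (or vector coercible to one) with exactly two
#'   levels, one entry per sample, or a named vector matched to
#'   `colnames(expr)`.
#' @return Named list of two matrices, one per condition level.
#' @export
split_by_condition <- function(expr, groups) {
  if (!is.null(names(groups))) {
    if (!all(colnames(expr) %in% names(groups)))
      stop("groups is named but does not cover all samples")
    groups <- groups[colnames(expr)]
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(expr))
    stop("groups must have one entry per sample")
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels, got ", nlevels(groups))
  stats::setNames(
    lapply(levels(groups), function(l) expr[, groups == l, drop = FALSE]),
    levels(groups))
}
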