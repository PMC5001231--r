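#' Generate a perfectly concordant expression matrix
#'
#' Emulates an idealized co-expressed module: a base profile drawn uniformly
#' on (0, 1) over N samples, and every other row an affine transform
#' `alpha * base + beta` with scale and shift also uniform on (0, 1). Every
#' pair of rows then has |Pearson correlation| = 1 exactly, so the raw
#' matrix has rank 2 and its centered, standardized form has rank 1.
#'
#' Scale draws below `min_alpha` are redrawn: an alpha of (numerically) zero
#' would create a constant row that cannot be standardized.
#'
#' @param n Number of genes (rows, >= 2).
#' @param N Number of samples (columns, >= 3).
#' @param min_alpha Smallest admissible scaling factor (default 1e-6).
#' @return n-by-N numeric matrix.
#' @examples
#' set.seed(7)
#' g <- make_correlated_matrix(5, 10)
#' range(abs(stats::cor(t(g))))  # all 1
#' @export
make_correlated_matrix <- function(n, N, min_alpha = 1e-6) {
  if (n < 2 || N < 3) stop("need n >= 2 and N >= 3")
  base <- stats::runif(N)
  alpha <- stats::runif(n - 1)
  while (any(alpha < min_alpha))
    alpha[alpha < min_alpha] <- stats::runif(sum(alpha < min_alpha))
  beta <- stats::runif(n - 1)
  rbind(base, alpha %o% base + beta, deparse.level = 0)
}

#' Add i.i.d. Gaussian noise to a matrix
#'
#' @param x Numeric matrix.
#' @param sigma Noise standard deviation (>= 0).
#' @return `x` plus independent N(0, sigma^2) perturbation of every entry;
#'   `sigma = 0` returns `x` unchanged.
#' @export
add_gaussian_noise <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  x + matrix(stats::rnorm(length(x), sd = sigma), nrow(x), ncol(x))
}

#' Relative Frobenius distortion of the transformed matrix
#'
#' Measures how much noise has moved the centered, row-standardized form of
#' a matrix: `R_F = ||Ghat_noisy - Ghat|| / ||Ghat||` in Frobenius norm,
#' both matrices transformed before comparison. Zero iff the transforms
#' coincide; 2 when every standardized row is exactly negated.
#'
#' @param noisy,clean Same-shape numeric matrices, neither with constant rows.
#' @return Non-negative scalar.
#' @export
frobenius_deviation_ratio <- function(noisy, clean) {
  if (!all(dim(noisy) == dim(clean))) stop("matrices must have the same shape")
  gh_n <- standardize_rows(centralize_rows(noisy))
  gh_c <- standardize_rows(centralize_rows(clean))
  norm(gh_n - gh_c, type = "F") / norm(gh_c, type = "F")
}

#' Append independently generated outlier rows
#'
#' Outliers are rows drawn i.i.d. uniform on (0, 1) — the same marginal as
#' the generator's base profile but independent of the module, so they are
#' uncorrelated with it in expectation.
#'
#' @param x Module matrix.
#' @param k Number of outlier rows to append (>= 0).
#' @return Matrix with `nrow(x) + k` rows.
#' @export
add_outlier_rows <- function(x, k) {
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(x)
  rbind(x, matrix(stats::runif(k * ncol(x)), k, ncol(x)), deparse.level = 0)
}

#' Stack two independently generated correlated modules
#'
#' Emulates the failure mode where a module-discovery algorithm erroneously
#' merges two distinct co-expressed modules: each block is generated with
#' [make_correlated_matrix()] plus Gaussian noise at `sigma`, and the blocks
#' are stacked. Cross-block correlations are incidental (near zero).
#'
#' @param n1,n2 Block sizes; `n2 = 0` yields just the first block.
#' @param N Number of samples.
#' @param sigma Noise level applied to each block.
#' @return (n1 + n2)-by-N matrix.
#' @export
make_interfering_modules <- function(n1, n2, N, sigma = 0) {
  if (n1 < 2) stop("n1 must be >= 2")
  if (n2 < 0) stop("n2 must be >= 0")
  block1 <- add_gaussian_noise(make_correlated_matrix(n1, N), sigma)
  if (n2 == 0) return(block1)
  if (n2 < 2) stop("n2 must be 0 or >= 2")
  block2 <- add_gaussian_noise(make_correlated_matrix(n2, N), sigma)
  rbind(block1, block2, deparse.level = 0)
}

#' Noise sweep: CCI degradation under increasing Gaussian noise
#'
#' For each noise level and repetition, generates a fresh perfectly
#' concordant matrix, perturbs it, and records the CCI together with the
#' relative Frobenius distortion `R_F` of the transformed matrix.
#'
#' @param n,N Module dimensions (defaults 50 genes by 100 samples).
#' @param sigma Noise-level grid (default the ten levels 0.01 to 1).
#' @param n_reps Repetitions per level (default 1000).
#' @param seed Optional integer seed.
#' @return Data frame with columns `sigma`, `rep`, `cci`, `r_f`.
#' @export
run_noise_sweep <- function(n = 50L, N = 100L,
                            sigma = c(0.01, 0.02, 0.05, 0.07, 0.1,
                                      0.15, 0.2, 0.3, 0.5, 1),
                            n_reps = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(n_reps), sigma = sigma)
  res <- t(mapply(function(s, r) {
    clean <- make_correlated_matrix(n, N)
    noisy <- add_gaussian_noise(clean, s)
    c(cci = .cci_stat(noisy),
      r_f = frobenius_deviation_ratio(noisy, clean))
  }, grid$sigma, grid$rep))
  data.frame(sigma = grid$sigma, rep = grid$rep,
             cci = res[, "cci"], r_f = res[, "r_f"])
}

#' Robustness comparison of CCI versus correlation density
#'
#' Reproduces the two stress scenarios used to benchmark the CCI against
#' the density metric:
#' \describe{
#'   \item{`"outliers"`}{a noisy concordant module of `n` genes is
#'     contaminated with an increasing number of independent outlier rows
#'     (nested across levels within a repetition, so curves are smooth);}
#'   \item{`"interference"`}{a second, independently generated concordant
#'     block of increasing size is stacked under the module.}
#' }
#' Both metrics are recorded per repetition at each contamination level and
#' each noise level, along with versions normalized to the same
#' repetition's uncontaminated (level 0) value.
#'
#' @param scenario `"outliers"` or `"interference"`.
#' @param n,N Module dimensions (defaults 50 by 100).
#' @param levels Contamination grid: outlier counts or interfering-block
#'   sizes (default 0 to `n` in steps of 5).
#' @param sigma Noise levels (default `c(0.05, 0.2)`).
#' @param n_reps Repetitions (default 100).
#' @param seed Optional integer seed.
#' @return Data frame with columns `scenario`, `sigma`, `level`, `rep`,
#'   `cci`, `density`, `cci_normalized`, `density_normalized`.
#' @export
run_robustness_comparison <- function(scenario = c("outliers", "interference"),
                                      n = 50L, N = 100L,
                                      levels = seq(0L, n, by = 5L),
                                      sigma = c(0.05, 0.2),
                                      n_reps = 100L, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!0 %in% levels)
    stop("levels must include 0 (the normalization reference)")
  levels <- sort(unique(as.integer(levels)))
  if (scenario == "interference" && any(levels == 1L))
    stop("an interfering block must have 0 or >= 2 genes")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(sigma) * n_reps)
  k <- 0L
  for (s in sigma) {
    for (r in seq_len(n_reps)) {
      module <- add_gaussian_noise(make_correlated_matrix(n, N), s)
      if (scenario == "outliers") {
        extra <- matrix(stats::runif(max(levels) * N), max(levels), N)
      } else {
        extra <- add_gaussian_noise(make_correlated_matrix(max(levels), N), s)
      }
      vals <- t(vapply(levels, function(lv) {
        m <- if (lv == 0) module else
          rbind(module, extra[seq_len(lv), , drop = FALSE], deparse.level = 0)
        c(.cci_stat(m), module_density(m))
      }, numeric(2)))
      k <- k + 1L
      rows[[k]] <- data.frame(
        scenario = scenario, sigma = s, level = levels, rep = r,
        cci = vals[, 1], density = vals[, 2],
        cci_normalized = vals[, 1] / vals[levels == 0, 1],
        density_normalized = vals[, 2] / vals[levels == 0, 2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
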