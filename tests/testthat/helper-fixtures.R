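# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# n rows that are exactly centered, unit-norm and mutually orthogonal
# (Helmert contrasts are orthogonal to the constant vector), so the
# gene-gene Pearson matrix is exactly the identity.
orthonormal_rows <- function(n, N) {
  stopifnot(n <= N - 1)
  q <- qr.Q(qr(stats::contr.helmert(N)))
  t(q[, seq_len(n), drop = FALSE])
}

# Two rows with Pearson correlation exactly rho, built from an orthonormal
# centered basis.
correlated_pair <- function(rho, N = 12) {
  b <- orthonormal_rows(2, N)
  rbind(b[1, ], rho * b[1, ] + sqrt(1 - rho^2) * b[2, ])
}

rand_mat <- function(n, N) matrix(rnorm(n * N), n, N)

# Background genome of i.i.d. uniform genes with identifiers.
noise_genome <- function(n_genes, n_samples) {
  matrix(runif(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# Independent CCI oracle: largest eigenvalue of the textbook Pearson
# correlation matrix of the rows, over n. Deliberately avoids the package's
# transform + SVD path.
cci_eigen_oracle <- function(x) {
  r <- stats::cor(t(x))
  eigen(r, symmetric = TRUE, only.values = TRUE)$values[1] / nrow(x)
}

write_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}
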