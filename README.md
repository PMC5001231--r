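# ccindex

Rank-based evaluation of gene co-expression modules with the **centralized
concordance index (CCI)**, plus resampling significance tests and a screen
for condition-specific co-expression.

## The problem and the statistic

Co-expression network tools (WGCNA, lmQCM, ...) emit *modules* — sets of
genes claimed to be mutually co-expressed — but give no rigorous criterion
for how concordant a module actually is. The linear-algebra condition is
simple: if every pair of rows of the genes × samples matrix
G ∈ ℝ<sup>n×N</sup> has |Pearson correlation| = 1, then each row is an
affine transform of one base profile, so rank(G) ≤ 2, and after centering
each row and scaling it to unit norm, the transformed matrix Ĝ has rank 1.

Two indices follow:

- **R12** = (S₁₁² + S₂₂²) / ‖G‖², the fraction of the squared Frobenius
  norm carried by the two leading singular values of the raw matrix;
  equal to 1 exactly under perfect pairwise correlation.
- **CCI** = Ŝ₁₁² / n, the squared leading singular value of the centered,
  row-standardized matrix over the module size. Because ĜĜᵀ is the
  gene–gene Pearson correlation matrix, CCI = λ<sub>max</sub>(R)/n: it
  ranges from 1/n (mutually uncorrelated genes) to 1 (perfect mutual
  correlation, signs arbitrary), and is invariant to per-gene affine
  rescaling, sign flips, and sample reordering.

Significance comes from two null models: within-row permutation
(`p_permute = #(CCI_p ≥ CCI)/M`) and, preferred, a z-score against the CCI
of M random same-size gene sets drawn from the whole dataset
(`Z_CCI = (CCI − mean(CCI_r)) / sd(CCI_r)`). A module is condition-specific
when Z_CCI meets the Bonferroni-adjusted one-tail threshold
τ = z<sub>1−α/m</sub> in one condition but not the other.

Compared with the classical module *density* (mean |correlation| over gene
pairs), the CCI is markedly more robust to outlier genes and to two
modules being erroneously merged; `run_robustness_comparison()` reproduces
that benchmark.

## Worked example

```r
library(ccindex)
set.seed(42)

# a 500-gene background with a noisy 40-gene concordant module planted in it
expr <- matrix(runif(500 * 30), 500, 30,
               dimnames = list(paste0("gene", 1:500), paste0("sample", 1:30)))
expr[1:40, ] <- add_gaussian_noise(make_correlated_matrix(40, 30), 0.1)
module <- paste0("gene", 1:40)

res <- cci(expr[module, ])
res
#> Centralized concordance index (n = 40 genes, N = 30 samples)
#>   CCI: 0.611324   (range 1/n = 0.025 to 1)
#>   R12 (raw matrix): 0.987169
#>   leading singular values of transformed matrix: 4.945, 1.4362, 1.3872, 1.2226, 1.1476, ...

null <- sample_random_module_null(expr, 40, M = 1000, seed = 42)
z <- cci_zscore(res$cci, null)
sprintf("null mean %.4f, sd %.4f, z = %.2f", null$mean, null$sd, z$z)
#> [1] "null mean 0.1138, sd 0.0157, z = 31.70"

module_density(expr[module, ])
#> [1] 0.5471
bonferroni_z_threshold(0.05, 10)   # tau when testing 10 modules
#> [1] 2.576
```

The module's CCI (0.61) says 61% of the transformed submatrix's energy sits
in one rank-1 component — far above the 0.11 expected of a random 40-gene
set from this dataset (z ≈ 32), so the module is strongly concordant.

For two conditions, `screen_modules(modules, expr_a, expr_b, alpha, M, seed)`
scores every module in both conditions against condition-matched nulls and
classifies each as `specific_to_a`, `specific_to_b`, `concordant_both` or
`concordant_neither`.

A command-line wrapper with `score`, `null`, `screen` and `simulate`
subcommands is at `system.file("cli", "cci.R", package = "ccindex")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cci.R",package="ccindex"))')" \
  score --expr expr.tsv --modules modules.gmt --out scores.tsv
```

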