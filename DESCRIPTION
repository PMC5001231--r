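Package: ccindex
Title: Centralized Concordance Index for Gene Co-Expression Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based evaluation of gene co-expression modules via the
    centralized concordance index (CCI), the squared leading singular value of
    the row-centered, row-standardized expression submatrix divided by module
    size. Provides the raw-matrix concordance index R12, the correlation
    density baseline, two null models for significance (within-row permutation
    and random gene-set z-scores with Bonferroni-adjusted thresholds),
    simulation generators for robustness benchmarking against the density
    metric, and a screening procedure for condition-specific co-expression
    modules. Modules are consumed as input (e.g. from lmQCM or WGCNA);
    module discovery itself is out of scope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
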