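Package: gmprnorm
Title: Robust Normalization of Zero-Inflated Count Data by Geometric Mean
    of Pairwise Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Size-factor normalization for zero-inflated feature-by-sample
    count tables such as 16S rDNA OTU tables. Implements the geometric mean
    of pairwise ratios (GMPR) estimator, which computes a median count ratio
    over the features shared by every pair of samples and synthesizes the
    pairwise ratios into one size factor per sample, together with the
    standard comparators (total-sum scaling, relative log expression with
    and without pseudo-counts, trimmed mean of M-values with and without
    pseudo-counts, and cumulative sum scaling). Includes Dirichlet-
    multinomial and zero-inflated negative-binomial simulators with
    perturbation schemes for benchmarking normalizations, a negative-
    binomial Wald test for differential abundance with size-factor offsets,
    and evaluation statistics (size-factor/library-size correlation,
    inter-sample variance ranking, paired signed-rank comparison, observed
    false discovery rate, ROC curves, and intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
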