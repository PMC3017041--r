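Package: eigensig
Title: PCA-Based Ranking of Differentially Expressed Genes Between Assay Groups
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks genes of an expression matrix by how differently they
    express between two assay groups identified from a principal component
    analysis. Implements the eigengene (correlation-based PCA of the
    gene-by-assay matrix) and eigenassay (covariance-based PCA of its
    transpose) contribution algebra, the differential-contribution statistic
    T_diff and its pooled-standard-deviation scaled form T_scaled, and the
    classical pooled two-sample t comparator. Signature sizes are chosen by
    the inflection method (largest drop in the ranked-statistic curve) or by
    a Storey-type q-value threshold on the pooled t. A Monte-Carlo
    simulation harness with planted differential genes measures top-k
    identification accuracy, statistical power, and false discovery rate of
    the three statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
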