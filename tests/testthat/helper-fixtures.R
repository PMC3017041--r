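# Fixture builders shared across the test files. All randomness is seeded
# locally so every test is replayable in isolation.

random_expression_matrix <- function(m = 20, n = 6, seed = 1, mean = 5.3,
                                     sd = 0.5) {
  set.seed(seed)
  expression_matrix(matrix(stats::rnorm(m * n, mean, sd), m, n))
}

# A ready-made half/half grouping for an n-assay matrix.
split_grouping <- function(n) {
  assay_grouping(seq_len(n %/% 2), (n %/% 2 + 1):n, n = n)
}

# Hand-built DifferentialResult (for signature-module tests that need exact
# statistic values without running a pipeline).
fake_result <- function(values, statistic = "t_diff", flagged = NULL) {
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  if (is.null(flagged)) flagged <- rep(FALSE, length(values))
  values[flagged] <- NA_real_
  structure(list(mode = "EG", pc_index = 1L, statistic = statistic,
                 values = values, flagged = flagged,
                 variance_estimates = NULL, pooled_sds = NULL),
            class = "DifferentialResult")
}

# Hand-built EG Decomposition with prescribed loading columns (orthonormality
# not required for the algebraic identities these serve).
fake_eg_decomposition <- function(loadings, scores = NULL) {
  loadings <- as.matrix(loadings)
  if (is.null(scores))
    scores <- matrix(0, nrow(loadings), ncol(loadings))
  structure(list(mode = "EG", loadings = loadings, scores = scores,
                 eigenvalues = rep(1, ncol(loadings)),
                 n_components = ncol(loadings)),
            class = "Decomposition")
}

write_matrix_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
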