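#' Construct an expression matrix
#'
#' Wraps an m genes x n assays matrix of real-valued expression levels
#' (log-scale intensities assumed but not enforced) together with unique
#' gene and assay identifiers. This is the input container for every
#' downstream operation.
#'
#' @param values Numeric matrix, m rows (genes) by n columns (assays),
#'   all entries finite.
#' @param gene_ids Character vector of m unique gene identifiers. Defaults
#'   to `rownames(values)`, or `gene_1 ... gene_m` when absent.
#' @param assay_ids Character vector of n unique assay identifiers.
#'   Defaults to `colnames(values)`, or `assay_1 ... assay_n` when absent.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, carrying the identifiers as dimnames),
#'   `gene_ids` and `assay_ids`.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 4, 3))
#' dim(x$values)
#' @export
expression_matrix <- function(values, gene_ids = NULL, assay_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  m <- nrow(values)
  n <- ncol(values)
  if (m < 2L || n < 2L)
    stop(sprintf("expression matrix must have >= 2 genes and >= 2 assays (got %d x %d)",
                 m, n), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  if (is.null(assay_ids)) assay_ids <- colnames(values)
  if (is.null(assay_ids)) assay_ids <- paste0("assay_", seq_len(n))
  gene_ids <- as.character(gene_ids)
  assay_ids <- as.character(assay_ids)
  if (length(gene_ids) != m)
    stop("length(gene_ids) does not match nrow(values)", call. = FALSE)
  if (length(assay_ids) != n)
    stop("length(assay_ids) does not match ncol(values)", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(assay_ids))
    stop("duplicate assay identifiers: ",
         paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(gene_ids, assay_ids)
  structure(list(values = values, gene_ids = gene_ids, assay_ids = assay_ids),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d assays\n",
              nrow(x$values), ncol(x$values)))
  cat("assays:", paste(utils::head(x$assay_ids, 8), collapse = ", "),
      if (length(x$assay_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Transpose an expression matrix, swapping gene and assay roles
#'
#' @param x An `ExpressionMatrix`.
#' @return An `ExpressionMatrix` with rows and columns exchanged.
#' @export
transpose_expression_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  expression_matrix(t(x$values), gene_ids = x$assay_ids, assay_ids = x$gene_ids)
}

#' Define a two-group assay assignment
#'
#' Groups A and B are disjoint, each non-empty, and together cover between 2
#' and n assays; they need not cover all assays. Indices are 1-based assay
#' column positions.
#'
#' @param group_a Integer vector of assay indices in Group A.
#' @param group_b Integer vector of assay indices in Group B (disjoint from
#'   `group_a`).
#' @param n Total number of assays in the matrix the grouping refers to
#'   (optional; enables bounds checking at construction).
#' @return An object of class `AssayGrouping` with elements `group_a`,
#'   `group_b`, `n_a`, `n_b`.
#' @examples
#' assay_grouping(1:5, 6:10, n = 10)
#' @export
assay_grouping <- function(group_a, group_b, n = NULL) {
  group_a <- as.integer(group_a)
  group_b <- as.integer(group_b)
  if (length(group_a) < 1L || length(group_b) < 1L)
    stop("both groups must contain at least one assay", call. = FALSE)
  if (anyDuplicated(group_a) || anyDuplicated(group_b))
    stop("duplicate assay indices within a group", call. = FALSE)
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups A and B must have no assays in common", call. = FALSE)
  if (any(group_a < 1L) || any(group_b < 1L))
    stop("assay indices must be >= 1", call. = FALSE)
  if (!is.null(n)) {
    if (length(group_a) + length(group_b) > n)
      stop("grouping covers more assays than the matrix has", call. = FALSE)
    if (any(c(group_a, group_b) > n))
      stop("grouping references assay indices beyond n = ", n, call. = FALSE)
  }
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(group_a), n_b = length(group_b)),
            class = "AssayGrouping")
}

#' @export
print.AssayGrouping <- function(x, ...) {
  cat(sprintf("AssayGrouping: A = {%s} (n_A = %d), B = {%s} (n_B = %d)\n",
              paste(x$group_a, collapse = ","), x$n_a,
              paste(x$group_b, collapse = ","), x$n_b))
  invisible(x)
}

# Validate a grouping against a matrix with n assays; returns it invisibly.
check_grouping <- function(g, n) {
  stopifnot(inherits(g, "AssayGrouping"))
  idx <- c(g$group_a, g$group_b)
  if (any(idx > n))
    stop("grouping references assay indices beyond the matrix (n = ", n, ")",
         call. = FALSE)
  invisible(g)
}

#' Bundle the user choices of one ranking run
#'
#' Binds the analysis mode (eigengene or eigenassay), the principal
#' component, the test statistic and the ranking direction into a single
#' validated record, mainly for the command-line interface and for logging.
#'
#' @param mode `"EG"` (correlation PCA of the gene x assay matrix) or
#'   `"EA"` (covariance PCA of its transpose).
#' @param pc_index 1-based principal component index.
#' @param statistic `"t_diff"`, `"t_scaled"` or `"t_pooled"`. `"t_scaled"`
#'   is rejected for mode `"EA"`, where scaling cancels the loading and
#'   reduces to the pooled t (exposed as `"t_pooled"`).
#' @param rank_by `"absolute"`, `"signed_descending"` or
#'   `"signed_ascending"`.
#' @param unit_variance Logical; use the unit-variance form of the scaled
#'   statistic (assumes standardized expression values have variance one).
#' @param seed Non-negative integer seed recorded for replayability.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(mode = c("EG", "EA"), pc_index = 1L,
                       statistic = c("t_diff", "t_scaled", "t_pooled"),
                       rank_by = c("absolute", "signed_descending",
                                   "signed_ascending"),
                       unit_variance = FALSE, seed = 0L) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  rank_by <- match.arg(rank_by)
  pc_index <- as.integer(pc_index)
  if (pc_index < 1L) stop("'pc_index' must be a positive integer", call. = FALSE)
  if (statistic == "t_scaled" && mode == "EA")
    stop("t_scaled is not defined for EA mode: the loading cancels and the ",
         "statistic reduces to the pooled t (use statistic = 't_pooled')",
         call. = FALSE)
  if (seed < 0) stop("'seed' must be non-negative", call. = FALSE)
  structure(list(mode = mode, pc_index = pc_index, statistic = statistic,
                 rank_by = rank_by, unit_variance = isTRUE(unit_variance),
                 seed = as.integer(seed)),
            class = "RunConfig")
}
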