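#' Read a tab-delimited expression matrix
#'
#' Expects UTF-8 tab-delimited text: the first row holds assay identifiers
#' (the top-left header cell is ignored), the first column holds gene
#' identifiers, and every remaining cell is a finite real with '.' as the
#' decimal separator. File order of genes and assays is preserved.
#'
#' @param path Path to the file.
#' @param transpose If `TRUE`, swap gene/assay roles after reading (for
#'   files stored one assay per row).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "", encoding = "UTF-8")
  if (ncol(tab) < 3L || nrow(tab) < 2L)
    stop("expression matrix file must have >= 2 gene rows and >= 2 assay columns",
         call. = FALSE)
  gene_ids <- tab[[1L]]
  assay_ids <- colnames(tab)[-1L]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("non-numeric cell '%s' at gene '%s' (row %d), assay '%s' (column %d)",
                 cells[i, j], gene_ids[i], i, assay_ids[j], j), call. = FALSE)
  }
  x <- expression_matrix(values, gene_ids = gene_ids, assay_ids = assay_ids)
  if (isTRUE(transpose)) transpose_expression_matrix(x) else x
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: identifiers round-trip exactly and
#' values round-trip to at least 15 significant digits.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(gene_id = x$gene_ids,
                    format(x$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", x$assay_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a ranked gene signature table
#'
#' Emits a tab-delimited file with columns `rank`, `gene_id`,
#' `statistic_value` and `in_signature` (1 for ranks up to the cutoff,
#' 0 beyond it). Rank 1 is the top of the configured ordering.
#'
#' @param result A `RankedSignature` (see [rank_genes()]).
#' @param path Output path.
#' @export
write_ranked_table <- function(result, path) {
  stopifnot(inherits(result, "RankedSignature"))
  m <- length(result$gene_order)
  tab <- data.frame(rank = seq_len(m),
                    gene_id = result$gene_order,
                    statistic_value = format(result$ranked_values, digits = 17,
                                             trim = TRUE),
                    in_signature = as.integer(seq_len(m) <= result$cutoff),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a ranked signature table
#'
#' @param path Path written by [write_ranked_table()].
#' @return A data.frame with columns rank, gene_id, statistic_value
#'   (numeric), in_signature.
#' @export
read_ranked_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = c("integer", "character", "numeric",
                                          "integer"),
                           encoding = "UTF-8")
  tab
}
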