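#' Quantify how well a principal component separates an assay grouping
#'
#' The visual step of choosing the component whose loading (EG) or score
#' (EA) plot separates the assays into the groups of interest, made numeric.
#' The per-assay values of component j are oriented so Group A's mean is at
#' least Group B's, then `gap` = min over A minus max over B: positive iff
#' every A assay sits above every B assay. `normalized_gap` divides the gap
#' by the larger within-group range, so a value of 1 means the gap between
#' the groups is as wide as the wider group's own spread; it is +Inf when
#' both groups have zero spread (and -Inf for a negative gap with zero
#' spread, 0 when all values coincide).
#'
#' @param d A `Decomposition`.
#' @param j 1-based principal component index.
#' @param g An `AssayGrouping` covering at least 2 assays.
#' @return An object of class `SeparationReport`: list with `pc_index`,
#'   `assay_values` (oriented), `gap`, `normalized_gap`, `separated`.
#' @export
separation_report <- function(d, j, g) {
  stopifnot(inherits(d, "Decomposition"))
  j <- .check_pc_index(j, d)
  assay_vals <- if (d$mode == "EG") d$loadings[, j] else d$scores[, j]
  check_grouping(g, length(assay_vals))
  a <- assay_vals[g$group_a]
  b <- assay_vals[g$group_b]
  if (mean(a) < mean(b)) {            # orient A above B before measuring
    assay_vals <- -assay_vals
    a <- -a
    b <- -b
  }
  gap <- min(a) - max(b)
  spread <- max(max(a) - min(a), max(b) - min(b))
  normalized_gap <- if (spread > 0) gap / spread
    else if (gap > 0) Inf else if (gap < 0) -Inf else 0
  structure(list(pc_index = j, assay_values = assay_vals, gap = gap,
                 normalized_gap = normalized_gap, separated = gap > 0),
            class = "SeparationReport")
}

#' @export
print.SeparationReport <- function(x, ...) {
  cat(sprintf("SeparationReport PC%d: gap = %.4g, normalized = %.4g, %s\n",
              x$pc_index, x$gap, x$normalized_gap,
              if (x$separated) "separated" else "not separated"))
  invisible(x)
}

#' Select the principal components that separate an assay grouping
#'
#' Returns the indices of all components whose oriented between-group gap
#' is positive and whose normalized gap meets the threshold, ordered by
#' normalized gap (descending), ties broken in favour of the lower
#' component index. An empty result is valid: no component need separate
#' the grouping. With few assays per group a chance separation is not
#' unlikely, so separation alone is never treated as significant.
#'
#' @param d A `Decomposition`.
#' @param g An `AssayGrouping`.
#' @param min_normalized_gap Non-negative threshold on the normalized gap;
#'   the default 1 demands a between-group gap at least as large as the
#'   wider within-group spread.
#' @return Integer vector of component indices (possibly empty).
#' @export
select_pcs <- function(d, g, min_normalized_gap = 1) {
  stopifnot(inherits(d, "Decomposition"), min_normalized_gap >= 0)
  reports <- lapply(seq_len(d$n_components), function(j)
    separation_report(d, j, g))
  ng <- vapply(reports, `[[`, numeric(1), "normalized_gap")
  sep <- vapply(reports, `[[`, logical(1), "separated")
  keep <- which(sep & ng >= min_normalized_gap)
  keep[order(-ng[keep], keep)]
}
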