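#' Rank genes by a differential statistic
#'
#' Stable sort of the per-gene statistic by the chosen key: `"absolute"`
#' (largest |value| first — the usual choice for two-sided interest),
#' `"signed_descending"` (most positive first) or `"signed_ascending"`
#' (most negative first). Ties keep input gene order; flagged genes
#' (zero-denominator sentinels) always occupy the final ranks.
#'
#' @param r A `DifferentialResult`.
#' @param rank_by One of `"absolute"`, `"signed_descending"`,
#'   `"signed_ascending"`.
#' @return An object of class `RankedSignature`: `gene_order` (ids, rank 1
#'   first), `ranked_values` (statistic in rank order; `NA` for flagged),
#'   `ranked_keys` (the nonincreasing sort key), `rank_by`, `cutoff`
#'   (initially 0), `method` (initially `"none"`), `n_flagged`.
#' @export
rank_genes <- function(r, rank_by = c("absolute", "signed_descending",
                                      "signed_ascending")) {
  stopifnot(inherits(r, "DifferentialResult"))
  rank_by <- match.arg(rank_by)
  values <- r$values
  flagged <- r$flagged
  if (all(flagged))
    stop("all genes are flagged (zero denominators); nothing to rank",
         call. = FALSE)
  ids <- names(values)
  if (is.null(ids)) ids <- paste0("gene_", seq_along(values))
  key <- switch(rank_by,
                absolute = abs(values),
                signed_descending = values,
                signed_ascending = -values)
  key[flagged] <- -Inf                 # flagged genes sink to the bottom
  ord <- order(-key, seq_along(key))   # stable: ties keep input order
  structure(list(gene_order = ids[ord],
                 ranked_values = unname(values[ord]),
                 ranked_keys = unname(key[ord]),
                 rank_by = rank_by,
                 cutoff = 0L,
                 method = "none",
                 n_flagged = sum(flagged)),
            class = "RankedSignature")
}

#' @export
print.RankedSignature <- function(x, ...) {
  cat(sprintf("RankedSignature: %d genes (%d flagged), rank_by = %s, cutoff = %d (%s)\n",
              length(x$gene_order), x$n_flagged, x$rank_by, x$cutoff,
              x$method))
  invisible(x)
}

#' Inflection-method signature cutoff
#'
#' Cuts the ranked list at the greatest change in the signature plot: the
#' cutoff is the rank r in `[search_min, search_max]` maximising the drop
#' key_r - key_{r+1} between consecutive ranked sort keys, ties resolved to
#' the smallest rank. Genes at ranks 1..cutoff form the signature.
#'
#' @param s A `RankedSignature` from [rank_genes()].
#' @param search_min Smallest candidate cutoff (default 1).
#' @param search_max Largest candidate cutoff; defaults to
#'   `min(m_unflagged - 1, 5000)` to keep degenerate tail gaps among
#'   flagged or near-zero genes out of the search.
#' @return The `RankedSignature` with `cutoff` set and
#'   `method = "inflection"`.
#' @export
inflection_cutoff <- function(s, search_min = 1L, search_max = NULL) {
  stopifnot(inherits(s, "RankedSignature"))
  m_ok <- length(s$gene_order) - s$n_flagged
  if (is.null(search_max)) search_max <- min(m_ok - 1L, 5000L)
  search_min <- as.integer(search_min)
  search_max <- as.integer(search_max)
  if (search_min < 1L || search_min >= search_max || search_max > m_ok - 1L)
    stop("need 1 <= search_min < search_max <= number of unflagged genes - 1",
         call. = FALSE)
  keys <- s$ranked_keys
  ranks <- search_min:search_max
  drops <- keys[ranks] - keys[ranks + 1L]
  if (all(drops == 0))
    stop("ranked values are constant in the search window; no inflection",
         call. = FALSE)
  s$cutoff <- ranks[which.max(drops)]  # which.max takes the first maximum
  s$method <- "inflection"
  s
}

#' Q-value signature cutoff on the pooled t-statistic
#'
#' The comparator method for sizing signatures: two-sided p-values from the
#' t reference distribution with n_A + n_B - 2 degrees of freedom, converted
#' to q-values with a single-lambda Storey estimate of the null proportion
#' (pi0 estimated at lambda = 0.5, clamped to `[1/m, 1]`); the signature is
#' every gene with q at most `max_q`, ranked by p ascending.
#'
#' q-values are step-up: q_(i) = pi0 * m * p_(i) / i, made monotone
#' nondecreasing in p by cumulative minima from the largest p downward and
#' capped at 1.
#'
#' @param t A `DifferentialResult` with `statistic = "t_pooled"`.
#' @param g The `AssayGrouping` the statistic was computed under (supplies
#'   the degrees of freedom).
#' @param max_q Maximum acceptable q-value, in (0, 1); default 0.05.
#' @return A `RankedSignature` (ranked by p ascending, flagged genes last)
#'   with `cutoff` set, `method = "qvalue"`, and extra elements `p_values`,
#'   `q_values` (in rank order) and `pi0`.
#' @export
qvalue_cutoff <- function(t, g, max_q = 0.05) {
  stopifnot(inherits(t, "DifferentialResult"))
  if (t$statistic != "t_pooled")
    stop("q-value cutoff is defined for the pooled t-statistic", call. = FALSE)
  if (!is.numeric(max_q) || max_q <= 0 || max_q >= 1)
    stop("'max_q' must lie strictly between 0 and 1", call. = FALSE)
  df <- g$n_a + g$n_b - 2L
  if (df < 1L) stop("degrees of freedom n_A + n_B - 2 must be >= 1",
                    call. = FALSE)
  s <- rank_genes(t, rank_by = "absolute")  # |t| descending == p ascending
  ok <- !is.na(s$ranked_values)
  m <- sum(ok)
  p <- 2 * stats::pt(-abs(s$ranked_values[ok]), df = df)
  pi0 <- sum(p > 0.5) / (m * 0.5)
  pi0 <- min(max(pi0, 1 / m), 1)
  q <- pi0 * m * p / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  s$p_values <- c(p, rep(NA_real_, s$n_flagged))
  s$q_values <- c(q, rep(NA_real_, s$n_flagged))
  s$pi0 <- pi0
  s$cutoff <- sum(q <= max_q)
  s$method <- "qvalue"
  s
}

#' Genes in the signature of a ranked list
#'
#' @param s A `RankedSignature` with its cutoff set.
#' @return Character vector of the gene ids at ranks 1..cutoff.
#' @export
signature_genes <- function(s) {
  stopifnot(inherits(s, "RankedSignature"))
  s$gene_order[seq_len(s$cutoff)]
}
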