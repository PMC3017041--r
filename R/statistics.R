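#' Per-gene eigengene group contributions
#'
#' For a chosen eigengene loading vector j, the contribution of assay k to
#' gene i's score is l_kj * z_ik. The group contribution of gene i is the
#' mean of these terms over the assays of the group:
#' gbar^A_i = (1/n_A) sum_{k in A} l_kj z_ik, and likewise for B.
#'
#' @param z A `StandardizedMatrix`.
#' @param d An EG `Decomposition`.
#' @param j 1-based principal component index.
#' @param g An `AssayGrouping`.
#' @return A `ContributionSet`: list with `mode`, `pc_index`,
#'   `per_gene_group_a`, `per_gene_group_b`, `grouping`.
#' @export
eg_group_contributions <- function(z, d, j, g) {
  stopifnot(inherits(z, "StandardizedMatrix"), inherits(d, "Decomposition"))
  if (d$mode != "EG") stop("decomposition must be in EG mode", call. = FALSE)
  j <- .check_pc_index(j, d)
  check_grouping(g, ncol(z$z_values))
  l <- d$loadings[, j]
  ga <- drop(z$z_values[, g$group_a, drop = FALSE] %*% l[g$group_a]) / g$n_a
  gb <- drop(z$z_values[, g$group_b, drop = FALSE] %*% l[g$group_b]) / g$n_b
  structure(list(mode = "EG", pc_index = j,
                 per_gene_group_a = ga, per_gene_group_b = gb, grouping = g),
            class = "ContributionSet")
}

#' Per-gene eigenassay group contributions
#'
#' For eigenassay loading vector j (one entry per gene), the group
#' contribution of gene p is its loading times the group mean of its raw
#' expression: gbar^A_p = l_pj * mean_{i in A}(x_pi), and likewise for B.
#'
#' @param x An `ExpressionMatrix`.
#' @param d An EA `Decomposition`.
#' @param j 1-based principal component index.
#' @param g An `AssayGrouping`.
#' @return A `ContributionSet`.
#' @export
ea_group_contributions <- function(x, d, j, g) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(d, "Decomposition"))
  if (d$mode != "EA") stop("decomposition must be in EA mode", call. = FALSE)
  j <- .check_pc_index(j, d)
  check_grouping(g, ncol(x$values))
  l <- d$loadings[, j]
  ga <- l * rowMeans(x$values[, g$group_a, drop = FALSE])
  gb <- l * rowMeans(x$values[, g$group_b, drop = FALSE])
  structure(list(mode = "EA", pc_index = j,
                 per_gene_group_a = ga, per_gene_group_b = gb, grouping = g),
            class = "ContributionSet")
}

.check_pc_index <- function(j, d) {
  j <- as.integer(j)
  if (j < 1L || j > d$n_components)
    stop("pc_index must be in 1..", d$n_components, call. = FALSE)
  j
}

.differential_result <- function(mode, pc_index, statistic, values,
                                 flagged = NULL, variance_estimates = NULL,
                                 pooled_sds = NULL) {
  if (is.null(flagged)) flagged <- rep(FALSE, length(values))
  values[flagged] <- NA_real_
  structure(list(mode = mode, pc_index = pc_index, statistic = statistic,
                 values = values, flagged = flagged,
                 variance_estimates = variance_estimates,
                 pooled_sds = pooled_sds),
            class = "DifferentialResult")
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf("DifferentialResult: %s (%s mode, PC%d), %d genes, %d flagged\n",
              x$statistic, x$mode, x$pc_index, length(x$values),
              sum(x$flagged)))
  invisible(x)
}

#' Differential contribution statistic T_diff
#'
#' The per-gene difference of group mean contributions,
#' T_diff = gbar^A - gbar^B. In EA mode this equals
#' l_pj * (xbar_Ap - xbar_Bp) identically.
#'
#' @param c A `ContributionSet` from [eg_group_contributions()] or
#'   [ea_group_contributions()].
#' @return A `DifferentialResult` with `statistic = "t_diff"`.
#' @export
t_diff <- function(c) {
  stopifnot(inherits(c, "ContributionSet"))
  .differential_result(c$mode, c$pc_index, "t_diff",
                       c$per_gene_group_a - c$per_gene_group_b)
}

#' Per-gene pooled standard deviation across two groups
#'
#' s2_pooled = [(n_A - 1) s2_A + (n_B - 1) s2_B] / (n_A + n_B - 2), computed
#' per gene (row). Both groups need at least two assays.
#'
#' @param values An m x n numeric matrix (standardized or raw expression).
#' @param g An `AssayGrouping` with n_a >= 2 and n_b >= 2.
#' @return Numeric vector of m pooled standard deviations (0 for genes
#'   constant within both groups).
#' @export
pooled_sd <- function(values, g) {
  stopifnot(is.matrix(values))
  check_grouping(g, ncol(values))
  if (g$n_a < 2L || g$n_b < 2L)
    stop("pooled standard deviation requires at least 2 assays per group",
         call. = FALSE)
  var_a <- .row_vars(values[, g$group_a, drop = FALSE])
  var_b <- .row_vars(values[, g$group_b, drop = FALSE])
  sqrt(((g$n_a - 1) * var_a + (g$n_b - 1) * var_b) / (g$n_a + g$n_b - 2))
}

# Row-wise sample variances (denominator n-1), vectorised.
.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Scaled eigengene statistic T_scaled
#'
#' T_diff divided by its estimated standard deviation, treating loadings as
#' fixed constants:
#' T_scaled_i = T_diff_i / ( s_pooled,z,i *
#'   sqrt( sum_{A} l^2 / n_A^2 + sum_{B} l^2 / n_B^2 ) ).
#' With `unit_variance = TRUE` the per-gene pooled standard deviation of the
#' standardized values is replaced by 1 — appropriate when assay variances
#' are all similar, so the standardized values are approximately N(0, 1).
#'
#' @param z A `StandardizedMatrix`.
#' @param d An EG `Decomposition`.
#' @param j 1-based principal component index.
#' @param g An `AssayGrouping` (each group needs >= 2 assays unless
#'   `unit_variance = TRUE`).
#' @param unit_variance Logical, default `FALSE`.
#' @return A `DifferentialResult` with `statistic = "t_scaled"`. Genes whose
#'   denominator is zero are flagged (`NA` value) rather than infinite.
#' @export
t_scaled_eg <- function(z, d, j, g, unit_variance = FALSE) {
  stopifnot(inherits(z, "StandardizedMatrix"), inherits(d, "Decomposition"))
  if (d$mode != "EG") stop("decomposition must be in EG mode", call. = FALSE)
  j <- .check_pc_index(j, d)
  check_grouping(g, ncol(z$z_values))
  l <- d$loadings[, j]
  loading_term <- sqrt(sum(l[g$group_a]^2) / g$n_a^2 +
                         sum(l[g$group_b]^2) / g$n_b^2)
  diff_vals <- t_diff(eg_group_contributions(z, d, j, g))$values
  if (unit_variance) {
    s_pool <- rep(1, length(diff_vals))
  } else {
    if (g$n_a < 2L || g$n_b < 2L)
      stop("t_scaled with estimated variance requires >= 2 assays per group; ",
           "use unit_variance = TRUE otherwise", call. = FALSE)
    s_pool <- pooled_sd(z$z_values, g)
  }
  denom <- s_pool * loading_term
  flagged <- unname(denom <= 0 | !is.finite(denom))
  values <- diff_vals / ifelse(flagged, NA_real_, denom)
  names(values) <- names(diff_vals)
  .differential_result("EG", j, "t_scaled", values, flagged,
                       variance_estimates = (denom)^2,
                       pooled_sds = s_pool)
}

#' Pooled two-sample t-statistic per gene
#'
#' The classical Student t on raw expression values,
#' t_p = (xbar_Ap - xbar_Bp) / ( s_pooled,x,p * sqrt(1/n_A + 1/n_B) ),
#' with n_A + n_B - 2 degrees of freedom. This is loading-free: scaling the
#' eigenassay differential contribution cancels the loading and lands
#' exactly here, which is why no scaled eigenassay statistic is exposed.
#'
#' @param x An `ExpressionMatrix`.
#' @param g An `AssayGrouping` with n_a >= 2 and n_b >= 2.
#' @return A `DifferentialResult` with `statistic = "t_pooled"` and
#'   `pc_index = NA` (no component involved). Zero-pooled-sd genes are
#'   flagged.
#' @export
t_pooled <- function(x, g) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  check_grouping(g, ncol(x$values))
  if (g$n_a < 2L || g$n_b < 2L)
    stop("pooled t requires at least 2 assays per group", call. = FALSE)
  mean_a <- rowMeans(x$values[, g$group_a, drop = FALSE])
  mean_b <- rowMeans(x$values[, g$group_b, drop = FALSE])
  s_pool <- pooled_sd(x$values, g)
  denom <- s_pool * sqrt(1 / g$n_a + 1 / g$n_b)
  flagged <- unname(denom <= 0 | !is.finite(denom))
  values <- (mean_a - mean_b) / ifelse(flagged, NA_real_, denom)
  names(values) <- x$gene_ids
  .differential_result("EA", NA_integer_, "t_pooled", values, flagged,
                       pooled_sds = s_pool)
}

#' Compute one of the three statistics from a configuration
#'
#' Convenience wrapper running the standardization/decomposition pipeline
#' appropriate to `config$mode` and returning the configured statistic for
#' the configured component. Orientation is fixed against the grouping.
#'
#' @param x An `ExpressionMatrix`.
#' @param g An `AssayGrouping`.
#' @param config A [run_config()].
#' @return A `DifferentialResult`.
#' @export
compute_statistic <- function(x, g, config) {
  stopifnot(inherits(config, "RunConfig"))
  if (config$statistic == "t_pooled") return(t_pooled(x, g))
  if (config$mode == "EG") {
    z <- standardize(x)
    d <- eigengene_decomposition(z, grouping = g)
    if (config$statistic == "t_diff")
      return(t_diff(eg_group_contributions(z, d, config$pc_index, g)))
    return(t_scaled_eg(z, d, config$pc_index, g,
                       unit_variance = config$unit_variance))
  }
  d <- eigenassay_decomposition(x, grouping = g)
  t_diff(ea_group_contributions(x, d, config$pc_index, g))
}
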