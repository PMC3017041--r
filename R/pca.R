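#' Standardize an expression matrix column-wise
#'
#' Each assay column is centred at its sample mean and scaled by its sample
#' standard deviation (denominator m - 1), giving the standardized matrix Z
#' used by the eigengene analysis: z_ij = (x_ij - mean_j) / sd_j.
#'
#' @param x An `ExpressionMatrix` with m >= 2 genes and no constant column.
#' @return An object of class `StandardizedMatrix`: list with `z_values`
#'   (m x n matrix), `column_means` and `column_sds`.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  mu <- colMeans(v)
  sd_ <- apply(v, 2L, stats::sd)
  degenerate <- which(sd_ <= 0 | !is.finite(sd_))
  if (length(degenerate) > 0L)
    stop("constant assay column(s) cannot be standardized: ",
         paste(x$assay_ids[degenerate], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(v, 2L, mu, "-"), 2L, sd_, "/")
  structure(list(z_values = z, column_means = mu, column_sds = sd_),
            class = "StandardizedMatrix")
}

# Shared assembly: order eigenpairs nonincreasing, clamp tiny eigenvalues.
.assemble_decomposition <- function(mode, loadings, scores, eigenvalues) {
  ord <- order(eigenvalues, decreasing = TRUE)
  eigenvalues <- eigenvalues[ord]
  loadings <- loadings[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  tiny <- eigenvalues < 1e-10 * max(eigenvalues, 0)
  eigenvalues[tiny | eigenvalues < 0] <- 0
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_along(eigenvalues))
  structure(list(mode = mode, loadings = loadings, scores = scores,
                 eigenvalues = eigenvalues, n_components = length(eigenvalues)),
            class = "Decomposition")
}

#' Eigengene decomposition (correlation-based PCA of the assays)
#'
#' Eigen-decomposes the n x n sample correlation matrix of the assays
#' (equivalently Z'Z / (m - 1)). Loading columns are the orthonormal
#' eigenvectors in nonincreasing eigenvalue order; scores are the pseudo
#' gene-expression values S = Z L. Component signs follow
#' [fix_orientation()].
#'
#' @param z A `StandardizedMatrix` from [standardize()].
#' @param grouping Optional `AssayGrouping` used to orient component signs.
#' @return A `Decomposition` with `mode = "EG"`: `loadings` n x n,
#'   `scores` m x n, `eigenvalues` summing to n.
#' @export
eigengene_decomposition <- function(z, grouping = NULL) {
  stopifnot(inherits(z, "StandardizedMatrix"))
  zm <- z$z_values
  n <- ncol(zm)
  if (n < 2L) stop("need at least 2 assays", call. = FALSE)
  r <- crossprod(zm) / (nrow(zm) - 1)
  r <- (r + t(r)) / 2  # guard symmetry against rounding
  e <- eigen(r, symmetric = TRUE)
  scores <- zm %*% e$vectors
  d <- .assemble_decomposition("EG", e$vectors, scores, e$values)
  fix_orientation(d, grouping)
}

#' Eigenassay decomposition (covariance-based PCA of the transpose)
#'
#' Treats genes as variables and assays as observations: the loadings are
#' the leading eigenvectors of the m x m sample covariance matrix of the
#' gene-centred data, computed through the n x n dual (Gram) problem so the
#' m x m matrix is never formed. Scores are taken from the raw, uncentred
#' values: S = X' L, matching the convention that the transpose analysis is
#' not standardized.
#'
#' @param x An `ExpressionMatrix`.
#' @param grouping Optional `AssayGrouping` used to orient component signs.
#' @return A `Decomposition` with `mode = "EA"`: `loadings` m x min(m, n)
#'   (gene space holds at most min(m, n) orthonormal directions),
#'   `scores` n x min(m, n), `eigenvalues` summing to the total gene-wise
#'   variance.
#' @export
eigenassay_decomposition <- function(x, grouping = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  n <- ncol(v)
  if (n < 2L) stop("need at least 2 assays", call. = FALSE)
  vc <- v - rowMeans(v)               # centre each gene across assays
  gram <- crossprod(vc) / (n - 1)     # n x n dual of the m x m covariance
  gram <- (gram + t(gram)) / 2
  e <- eigen(gram, symmetric = TRUE)
  # gene space holds at most min(m, n) orthonormal directions
  k_total <- min(nrow(v), n)
  lam <- pmax(e$values, 0)[seq_len(k_total)]
  loadings <- matrix(0, nrow(v), k_total)
  nonzero <- lam > 1e-12 * max(lam, .Machine$double.eps)
  if (any(nonzero)) {
    u <- vc %*% e$vectors[, which(nonzero), drop = FALSE]
    u <- sweep(u, 2L, sqrt(colSums(u^2)), "/")
    loadings[, nonzero] <- u
  }
  if (any(!nonzero)) {
    # zero-variance directions: deterministic orthonormal completion via QR
    basis <- qr.Q(qr(cbind(loadings[, nonzero, drop = FALSE],
                           diag(nrow(v))[, seq_len(sum(!nonzero)),
                                         drop = FALSE])))
    loadings[, !nonzero] <- basis[, sum(nonzero) + seq_len(sum(!nonzero)),
                                  drop = FALSE]
  }
  scores <- t(v) %*% loadings         # raw (uncentred) values by convention
  d <- .assemble_decomposition("EA", loadings, scores, lam)
  fix_orientation(d, grouping)
}

#' Fix the arbitrary signs of principal components
#'
#' Eigenvector signs are mathematically arbitrary; this makes them
#' deterministic. With a grouping, each component is flipped so that the
#' mean over Group A minus the mean over Group B of its assay-wise values
#' (EG: loading entries; EA: score entries) is non-negative. Without a
#' grouping, the largest-magnitude loading entry is made positive. Loading
#' and score columns are always flipped together, so all reconstruction
#' identities are preserved. Idempotent.
#'
#' @param d A `Decomposition`.
#' @param grouping Optional `AssayGrouping`.
#' @return The `Decomposition` with oriented components.
#' @export
fix_orientation <- function(d, grouping = NULL) {
  stopifnot(inherits(d, "Decomposition"))
  assay_vals <- if (d$mode == "EG") d$loadings else d$scores
  for (j in seq_len(d$n_components)) {
    if (!is.null(grouping)) {
      check_grouping(grouping, nrow(assay_vals))
      contrast <- mean(assay_vals[grouping$group_a, j]) -
        mean(assay_vals[grouping$group_b, j])
      flip <- contrast < 0
    } else {
      lead <- which.max(abs(d$loadings[, j]))
      flip <- d$loadings[lead, j] < 0
    }
    if (flip) {
      d$loadings[, j] <- -d$loadings[, j]
      d$scores[, j] <- -d$scores[, j]
      assay_vals[, j] <- -assay_vals[, j]
    }
  }
  d
}

#' @export
print.Decomposition <- function(x, ...) {
  pv <- if (sum(x$eigenvalues) > 0) x$eigenvalues / sum(x$eigenvalues) else
    rep(NA_real_, x$n_components)
  cat(sprintf("Decomposition (%s): %d components\n", x$mode, x$n_components))
  cat("eigenvalues:", paste(signif(utils::head(x$eigenvalues, 6), 4),
                            collapse = ", "),
      if (x$n_components > 6) "..." else "", "\n")
  cat("prop. variance (PC1):", signif(pv[1L], 4), "\n")
  invisible(x)
}
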