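# Brute-force loop oracle for group contributions: term-by-term summation.
loop_eg_contributions <- function(z, loadings, j, members) {
  sapply(seq_len(nrow(z)), function(i)
    mean(sapply(members, function(k) loadings[k, j] * z[i, k])))
}

test_that("eigengene group contributions match a loop-based oracle", {
  x <- random_expression_matrix(m = 4, n = 4, seed = 5)
  z <- standardize(x)
  g <- assay_grouping(c(1, 3), c(2, 4), n = 4)
  d <- eigengene_decomposition(z, grouping = g)
  for (j in 1:4) {
    cs <- eg_group_contributions(z, d, j, g)
    expect_equal(unname(cs$per_gene_group_a),
                 loop_eg_contributions(z$z_values, d$loadings, j, g$group_a),
                 tolerance = 1e-12)
    expect_equal(unname(cs$per_gene_group_b),
                 loop_eg_contributions(z$z_values, d$loadings, j, g$group_b),
                 tolerance = 1e-12)
  }

  # singleton group: the contribution is the single weighted term
  g1 <- assay_grouping(2, c(1, 3), n = 4)
  cs1 <- eg_group_contributions(z, d, 1, g1)
  expect_equal(unname(cs1$per_gene_group_a),
               unname(d$loadings[2, 1] * z$z_values[, 2]), tolerance = 1e-12)

  # constant loadings reduce to loading times the group mean
  dflat <- fake_eg_decomposition(matrix(0.5, 4, 1))
  csf <- eg_group_contributions(z, dflat, 1, g)
  expect_equal(unname(csf$per_gene_group_a),
               unname(0.5 * rowMeans(z$z_values[, g$group_a])),
               tolerance = 1e-12)
})

test_that("eigenassay group contributions are loading times raw group mean", {
  x <- random_expression_matrix(m = 12, n = 6, seed = 6)
  g <- split_grouping(6)
  d <- eigenassay_decomposition(x, grouping = g)
  cs <- ea_group_contributions(x, d, 1, g)
  expect_equal(unname(cs$per_gene_group_a),
               unname(d$loadings[, 1] * rowMeans(x$values[, g$group_a])),
               tolerance = 1e-12)
  # loop oracle on the summation form
  oracle <- sapply(seq_len(12), function(p)
    mean(sapply(g$group_b, function(i) d$loadings[p, 1] * x$values[p, i])))
  expect_equal(unname(cs$per_gene_group_b), oracle, tolerance = 1e-12)
})

test_that("contributions decompose the score exactly", {
  x <- random_expression_matrix(m = 30, n = 5, seed = 8)
  z <- standardize(x)
  d <- eigengene_decomposition(z)
  # summing every assay's contribution recovers the score
  for (j in 1:5) {
    total <- rowSums(sweep(z$z_values, 2, d$loadings[, j], "*"))
    expect_equal(total, unname(d$scores[, j]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("t_diff differences contributions, with the EA two-path identity", {
  x <- random_expression_matrix(m = 15, n = 6, seed = 9)
  g <- split_grouping(6)
  d <- eigenassay_decomposition(x, grouping = g)
  td <- t_diff(ea_group_contributions(x, d, 2, g))
  direct <- d$loadings[, 2] * (rowMeans(x$values[, g$group_a]) -
                                 rowMeans(x$values[, g$group_b]))
  expect_equal(unname(td$values), unname(direct), tolerance = 1e-12)

  # identical groups in value give all-zero differences
  xdup <- expression_matrix(x$values[, c(1:3, 1:3)],
                            assay_ids = paste0("a", 1:6))
  ddup <- eigenassay_decomposition(xdup)
  tdup <- t_diff(ea_group_contributions(xdup, ddup, 1, split_grouping(6)))
  expect_equal(max(abs(tdup$values)), 0, tolerance = 1e-12)

  # anti-symmetry under swapping the groups (same decomposition)
  g_swap <- assay_grouping(g$group_b, g$group_a, n = 6)
  td_swap <- t_diff(ea_group_contributions(x, d, 2, g_swap))
  expect_equal(td_swap$values, -td$values, tolerance = 1e-12)
})

test_that("pooled sd applies the weighted-variance formula", {
  # equal variances: pooled variance equals the common variance
  vals <- rbind(g1 = c(1, 3, 2, 4))
  vals <- rbind(vals, g2 = c(0, 0, 1, 1))
  g <- assay_grouping(1:2, 3:4, n = 4)
  expect_equal(unname(pooled_sd(vals, g))[1], sqrt(2), tolerance = 1e-12)

  # unbalanced weights: n_A = 3 (var 1), n_B = 2 (var 4) -> pooled var 2
  a <- c(0, 1, 2)                     # sample variance 1
  b <- c(0, 2 * sqrt(2))              # sample variance 4
  m2 <- rbind(x = c(a, b), y = c(a, b) + 1)
  g2 <- assay_grouping(1:3, 4:5, n = 5)
  expect_equal(unname(pooled_sd(m2, g2)), rep(sqrt(2), 2), tolerance = 1e-12)

  # balanced groups: simple average of the two variances
  set.seed(10)
  m3 <- matrix(rnorm(40), 5, 8)
  g3 <- split_grouping(8)
  va <- apply(m3[, 1:4], 1, var)
  vb <- apply(m3[, 5:8], 1, var)
  expect_equal(unname(pooled_sd(m3, g3)), sqrt((va + vb) / 2),
               tolerance = 1e-12)

  expect_error(pooled_sd(m2, assay_grouping(1:4, 5, n = 5)),
               "at least 2")
})

test_that("the scaled statistic follows its algebraic simplifications", {
  x <- random_expression_matrix(m = 25, n = 6, seed = 13)
  z <- standardize(x)
  g <- split_grouping(6)

  # equal loadings, balanced groups, unit variance:
  # value = (zbar_A - zbar_B) * sqrt(q / 2), independent of the loading
  for (ell in c(0.3, 1, 2.5)) {
    dflat <- fake_eg_decomposition(matrix(ell, 6, 1))
    ts <- t_scaled_eg(z, dflat, 1, g, unit_variance = TRUE)
    q <- g$n_a
    expected <- (rowMeans(z$z_values[, g$group_a]) -
                   rowMeans(z$z_values[, g$group_b])) * sqrt(q / 2)
    expect_equal(unname(ts$values), unname(expected), tolerance = 1e-12)
  }

  # scale equivariance: c > 0 times the loading vector leaves it unchanged
  d <- eigengene_decomposition(z, grouping = g)
  ts1 <- t_scaled_eg(z, d, 1, g, unit_variance = TRUE)
  d_scaled <- d
  d_scaled$loadings[, 1] <- 3.7 * d_scaled$loadings[, 1]
  ts2 <- t_scaled_eg(z, d_scaled, 1, g, unit_variance = TRUE)
  expect_equal(ts2$values, ts1$values, tolerance = 1e-12)

  # anti-symmetry under group swap
  g_swap <- assay_grouping(g$group_b, g$group_a, n = 6)
  expect_equal(t_scaled_eg(z, d, 1, g_swap)$values,
               -t_scaled_eg(z, d, 1, g)$values, tolerance = 1e-12)

  # zero loadings on every grouped assay: all genes flagged, no infinities
  dzero <- fake_eg_decomposition(matrix(0, 6, 1))
  tsz <- t_scaled_eg(z, dzero, 1, g)
  expect_true(all(tsz$flagged))
  expect_true(all(is.na(tsz$values)))
})

test_that("the pooled t matches both the hand formula and t.test", {
  x <- expression_matrix(rbind(g1 = c(1, 2, 3, 4, 5, 6),
                               g2 = c(2, 2, 4, 4, 6, 6)))
  g <- assay_grouping(1:3, 4:6, n = 6)
  tp <- t_pooled(x, g)
  # A = (1,2,3), B = (4,5,6): mean diff -3, pooled var 1
  expect_equal(unname(tp$values[1]), -3 / sqrt(2 / 3), tolerance = 1e-12)

  xr <- random_expression_matrix(m = 10, n = 7, seed = 14)
  gr <- assay_grouping(1:4, 5:7, n = 7)
  tpr <- t_pooled(xr, gr)
  oracle <- apply(xr$values, 1, function(row)
    stats::t.test(row[1:4], row[5:7], var.equal = TRUE)$statistic)
  expect_equal(unname(tpr$values), unname(oracle), tolerance = 1e-10)

  # equal group means give zero; anti-symmetry under swap
  xe <- expression_matrix(rbind(c(1, 2, 1, 2), c(0, 4, 4, 0)))
  te <- t_pooled(xe, assay_grouping(1:2, 3:4, n = 4))
  expect_equal(unname(te$values), c(0, 0))
  g_swap <- assay_grouping(5:7, 1:4, n = 7)
  expect_equal(t_pooled(xr, g_swap)$values, -tpr$values, tolerance = 1e-12)

  # genes constant within both groups get flagged, never infinite
  xc <- expression_matrix(rbind(c(1, 1, 2, 2), c(1, 2, 3, 4)))
  tc <- t_pooled(xc, assay_grouping(1:2, 3:4, n = 4))
  expect_true(tc$flagged[1])
  expect_true(is.na(tc$values[1]))
  expect_false(tc$flagged[2])
})

test_that("scaling the EA differential contribution recovers the pooled t exactly", {
  # the loading cancels: the symbolically scaled EA statistic IS Student's t
  for (seed in 1:20) {
    x <- random_expression_matrix(m = 12, n = 6, seed = 100 + seed)
    g <- split_grouping(6)
    d <- eigenassay_decomposition(x, grouping = g)
    j <- 1 + seed %% 3
    l <- d$loadings[, j]
    td <- t_diff(ea_group_contributions(x, d, j, g))
    denom <- l * pooled_sd(x$values, g) * sqrt(1 / g$n_a + 1 / g$n_b)
    scaled_ea <- td$values / denom
    tp <- t_pooled(x, g)
    ok <- abs(l) > 1e-12 & !tp$flagged
    expect_true(all(abs(scaled_ea[ok] - tp$values[ok]) < 1e-12))
  }
})

test_that("affine transforms act on the statistics as the algebra predicts", {
  x <- random_expression_matrix(m = 20, n = 6, seed = 15)
  g <- split_grouping(6)
  a <- -2.5; b <- 7
  xa <- expression_matrix(a * x$values + b, gene_ids = x$gene_ids,
                          assay_ids = x$assay_ids)

  # pooled t invariant up to the sign of a
  expect_equal(t_pooled(xa, g)$values, sign(a) * t_pooled(x, g)$values,
               tolerance = 1e-10)

  # EA differential contribution scales by |a|
  d <- eigenassay_decomposition(x, grouping = g)
  da <- eigenassay_decomposition(xa, grouping = g)
  td <- t_diff(ea_group_contributions(x, d, 1, g))
  tda <- t_diff(ea_group_contributions(xa, da, 1, g))
  expect_equal(abs(tda$values), abs(a) * abs(td$values), tolerance = 1e-10)
})

test_that("compute_statistic dispatches the configured pipeline", {
  x <- random_expression_matrix(m = 30, n = 6, seed = 16)
  g <- split_grouping(6)
  r1 <- compute_statistic(x, g, run_config(mode = "EG", statistic = "t_diff"))
  z <- standardize(x)
  d <- eigengene_decomposition(z, grouping = g)
  expect_equal(r1$values, t_diff(eg_group_contributions(z, d, 1, g))$values)
  r2 <- compute_statistic(x, g, run_config(statistic = "t_pooled"))
  expect_equal(r2$values, t_pooled(x, g)$values)
})
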