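#' Configuration of the planted-gene simulation
#'
#' Describes one condition of the Monte-Carlo study used to benchmark the
#' ranking statistics. Each simulated matrix has `m` genes and `n` assays
#' split into Group A (the first `n_a` columns) and Group B (the rest).
#' Every cell is an independent normal draw with standard deviation
#' sigma_i (per gene) around `baseline_mean`, except that the first
#' `n_sdg` genes are shifted up by `delta` in the Group-A assays — these
#' are the planted significantly different genes (SDG) the methods must
#' recover.
#'
#' Two noise regimes are supported. `"constant"`: every gene has the same
#' sigma. `"lognormal"`: each gene draws its own sigma once from a
#' lognormal distribution; by default the stated mean and variance are on
#' the natural scale (mean 0.37, variance 0.37^2, hence log-scale variance
#' ln 2), with `lognormal_on_log_scale = TRUE` reinterpreting them as the
#' log-scale parameters instead.
#'
#' @param m Number of genes (default 40000).
#' @param n Number of assays (default 10); must equal `n_a + n_b`.
#' @param n_a,n_b Group sizes (default 5 and 5).
#' @param n_sdg Number of planted differential genes (default 200).
#' @param baseline_mean Background mean expression (default 5.3).
#' @param delta Differential shift added to SDG cells in Group A
#'   (default 1; 0 gives a null dataset).
#' @param sigma_regime `"constant"` or `"lognormal"`.
#' @param sigma Per-gene standard deviation in the constant regime
#'   (default 0.2).
#' @param lognormal_mean,lognormal_variance Natural-scale mean and variance
#'   of the per-gene sigma distribution in the lognormal regime (defaults
#'   0.37 and 0.37^2).
#' @param lognormal_on_log_scale If `TRUE`, treat `lognormal_mean` and
#'   `lognormal_variance` as the mean and variance of log(sigma) instead.
#' @param trials Number of Monte-Carlo trials a benchmark averages over
#'   (default 5).
#' @param seed Base seed; together with a trial index it fully determines
#'   every generated value.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(m = 40000L, n = 10L, n_a = 5L, n_b = 5L,
                              n_sdg = 200L, baseline_mean = 5.3, delta = 1,
                              sigma_regime = c("constant", "lognormal"),
                              sigma = 0.2,
                              lognormal_mean = 0.37,
                              lognormal_variance = 0.37^2,
                              lognormal_on_log_scale = FALSE,
                              trials = 5L, seed = 0L) {
  sigma_regime <- match.arg(sigma_regime)
  m <- as.integer(m); n <- as.integer(n)
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  n_sdg <- as.integer(n_sdg); trials <- as.integer(trials)
  if (n_a + n_b != n) stop("n_a + n_b must equal n", call. = FALSE)
  if (n_sdg > m) stop("n_sdg cannot exceed m", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (sigma_regime == "constant" && sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  if (sigma_regime == "lognormal" &&
      (lognormal_mean <= 0 || lognormal_variance <= 0))
    stop("lognormal parameters must be positive", call. = FALSE)
  if (trials < 1L) stop("trials must be >= 1", call. = FALSE)
  if (seed < 0) stop("seed must be non-negative", call. = FALSE)
  structure(list(m = m, n = n, n_a = n_a, n_b = n_b, n_sdg = n_sdg,
                 baseline_mean = baseline_mean, delta = delta,
                 sigma_regime = sigma_regime, sigma = sigma,
                 lognormal_mean = lognormal_mean,
                 lognormal_variance = lognormal_variance,
                 lognormal_on_log_scale = isTRUE(lognormal_on_log_scale),
                 trials = trials, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Deterministic per-trial seed below 2^31, decoupling trials from each other.
.trial_seed <- function(seed, trial_index) {
  as.integer((as.double(seed) + 1000003 * as.double(trial_index)) %% 2147483647)
}

#' Generate one simulated expression dataset with planted truth
#'
#' Draws the matrix described by a [simulation_config()]. Bit-identical
#' output for identical `(config$seed, trial_index)`, and independent of
#' how many other trials are run.
#'
#' @param config A `SimulationConfig`.
#' @param trial_index 1-based trial number.
#' @return A list: `matrix` (an `ExpressionMatrix`), `truth_ids`
#'   (gene ids of the planted SDG), `truth_idx` (their row indices),
#'   `grouping` (the generating `AssayGrouping`: A = first `n_a` assays),
#'   `sigmas` (the per-gene standard deviations used).
#' @export
generate_dataset <- function(config, trial_index = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  trial_index <- as.integer(trial_index)
  if (trial_index < 1L) stop("trial_index must be >= 1", call. = FALSE)
  set.seed(.trial_seed(config$seed, trial_index))
  m <- config$m; n <- config$n
  if (config$sigma_regime == "constant") {
    sigmas <- rep(config$sigma, m)
  } else {
    if (config$lognormal_on_log_scale) {
      meanlog <- config$lognormal_mean
      sdlog <- sqrt(config$lognormal_variance)
    } else {
      sdlog2 <- log(1 + config$lognormal_variance / config$lognormal_mean^2)
      meanlog <- log(config$lognormal_mean) - sdlog2 / 2
      sdlog <- sqrt(sdlog2)
    }
    sigmas <- stats::rlnorm(m, meanlog = meanlog, sdlog = sdlog)
  }
  values <- config$baseline_mean +
    matrix(stats::rnorm(m * n), m, n) * sigmas   # sigma_i recycled down rows
  if (config$n_sdg > 0L && config$delta > 0)
    values[seq_len(config$n_sdg), seq_len(config$n_a)] <-
      values[seq_len(config$n_sdg), seq_len(config$n_a)] + config$delta
  gene_ids <- sprintf("gene_%05d", seq_len(m))
  assay_ids <- c(sprintf("A%d", seq_len(config$n_a)),
                 sprintf("B%d", seq_len(config$n_b)))
  list(matrix = expression_matrix(values, gene_ids, assay_ids),
       truth_ids = gene_ids[seq_len(config$n_sdg)],
       truth_idx = seq_len(config$n_sdg),
       grouping = assay_grouping(seq_len(config$n_a),
                                 config$n_a + seq_len(config$n_b), n = n),
       sigmas = sigmas)
}

#' Percentage of planted genes captured in the top k ranks
#'
#' @param s A `RankedSignature`.
#' @param truth Character vector of planted gene ids (non-empty).
#' @param k Number of top ranks to inspect (at most the number of genes).
#' @return 100 * |top-k genes intersect truth| / |truth|.
#' @export
pct_sdg_in_top_k <- function(s, truth, k) {
  stopifnot(inherits(s, "RankedSignature"))
  if (length(truth) == 0L) stop("'truth' must be non-empty", call. = FALSE)
  k <- as.integer(k)
  if (k > length(s$gene_order))
    stop("k exceeds the number of ranked genes", call. = FALSE)
  100 * length(intersect(s$gene_order[seq_len(k)], truth)) / length(truth)
}
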