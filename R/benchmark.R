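# Monte-Carlo benchmark harness: top-k recovery, power and FDR of the
# ranking statistics on simulated data with planted differential genes.

# Rank one simulated dataset by each statistic; returns named list of
# RankedSignature objects (absolute-value ranking throughout).
.rank_all_statistics <- function(dataset, unit_variance = FALSE,
                                 include_ea = FALSE) {
  x <- dataset$matrix
  g <- dataset$grouping
  z <- standardize(x)
  d <- eigengene_decomposition(z, grouping = g)
  out <- list(
    t_diff = rank_genes(t_diff(eg_group_contributions(z, d, 1L, g)),
                        "absolute"),
    t_scaled = rank_genes(t_scaled_eg(z, d, 1L, g,
                                      unit_variance = unit_variance),
                          "absolute"),
    t_pooled = rank_genes(t_pooled(x, g), "absolute"))
  if (include_ea) {
    da <- eigenassay_decomposition(x, grouping = g)
    out$t_diff_ea <- rank_genes(t_diff(ea_group_contributions(x, da, 1L, g)),
                                "absolute")
  }
  out
}

.average_trials <- function(per_trial, by_cols, value_col = "pct") {
  agg <- stats::aggregate(per_trial[[value_col]], per_trial[by_cols], mean)
  names(agg)[ncol(agg)] <- value_col
  agg
}

#' Benchmark top-k recovery across noise levels (constant-variance study)
#'
#' For each noise level sigma: generate `trials` datasets with planted
#' differential genes, run the eigengene pipeline (standardize, PC1 of the
#' correlation decomposition, orient by the group contrast), rank genes by
#' |T_diff|, |T_scaled| and |pooled t|, and record the percentage of the
#' planted genes captured in the top k ranks for each k. Results are
#' averaged over trials.
#'
#' @param sigma_grid Noise standard deviations to sweep (default
#'   `c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0)`, i.e. variances 0.04 to 1).
#' @param delta Planted shift (default 1).
#' @param trials Trials per grid point (default 5).
#' @param seed Base seed.
#' @param k_values Top-rank depths to report (default `c(200, 300, 400)`).
#' @param config Template [simulation_config()] supplying the remaining
#'   generator parameters (sizes, baseline); its `sigma`, `delta`,
#'   `sigma_regime`, `trials` and `seed` fields are overridden per call.
#' @param unit_variance Use the unit-variance form of T_scaled.
#' @param include_ea Also rank by the eigenassay-mode T_diff
#'   (statistic label `"t_diff_ea"`).
#' @return A data.frame with columns `sigma`, `delta`, `statistic`, `k`,
#'   `pct` (trial-averaged capture percentage), `trials`, `seed`; the
#'   per-trial values are attached as `attr(, "per_trial")`.
#' @export
run_part1 <- function(sigma_grid = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0),
                      delta = 1, trials = 5L, seed = 0L,
                      k_values = c(200L, 300L, 400L),
                      config = simulation_config(),
                      unit_variance = FALSE, include_ea = FALSE) {
  stopifnot(length(sigma_grid) >= 1L)
  rows <- list()
  for (sigma in sigma_grid) {
    cfg <- simulation_config(m = config$m, n = config$n, n_a = config$n_a,
                             n_b = config$n_b, n_sdg = config$n_sdg,
                             baseline_mean = config$baseline_mean,
                             delta = delta, sigma_regime = "constant",
                             sigma = sigma, trials = trials, seed = seed)
    for (trial in seq_len(trials)) {
      ds <- generate_dataset(cfg, trial)
      ranked <- .rank_all_statistics(ds, unit_variance = unit_variance,
                                     include_ea = include_ea)
      for (stat in names(ranked)) for (k in k_values)
        rows[[length(rows) + 1L]] <- data.frame(
          sigma = sigma, delta = delta, statistic = stat, k = k,
          trial = trial, pct = pct_sdg_in_top_k(ranked[[stat]],
                                                ds$truth_ids, k))
    }
  }
  per_trial <- do.call(rbind, rows)
  out <- .average_trials(per_trial, c("sigma", "delta", "statistic", "k"))
  out$trials <- trials
  out$seed <- seed
  attr(out, "per_trial") <- per_trial
  out
}

#' Benchmark top-k recovery under gene-specific noise (lognormal study)
#'
#' Same pipeline as [run_part1()] but each gene draws its own standard
#' deviation from the lognormal regime of the generator, and the planted
#' shift is swept instead of the noise level.
#'
#' @param delta_values Planted shifts to sweep (default `c(1, 3)`).
#' @param trials Trials per shift (default 5).
#' @param seed Base seed.
#' @param k_values Top-rank depths to report (default `c(200, 400)`).
#' @param config Template [simulation_config()] (see [run_part1()]).
#' @param unit_variance,include_ea As in [run_part1()].
#' @return A data.frame as in [run_part1()] (no `sigma` column; the noise
#'   regime is lognormal).
#' @export
run_part2 <- function(delta_values = c(1, 3), trials = 5L, seed = 0L,
                      k_values = c(200L, 400L),
                      config = simulation_config(),
                      unit_variance = FALSE, include_ea = FALSE) {
  stopifnot(length(delta_values) >= 1L)
  rows <- list()
  for (delta in delta_values) {
    cfg <- simulation_config(m = config$m, n = config$n, n_a = config$n_a,
                             n_b = config$n_b, n_sdg = config$n_sdg,
                             baseline_mean = config$baseline_mean,
                             delta = delta, sigma_regime = "lognormal",
                             lognormal_mean = config$lognormal_mean,
                             lognormal_variance = config$lognormal_variance,
                             lognormal_on_log_scale = config$lognormal_on_log_scale,
                             trials = trials, seed = seed)
    for (trial in seq_len(trials)) {
      ds <- generate_dataset(cfg, trial)
      ranked <- .rank_all_statistics(ds, unit_variance = unit_variance,
                                     include_ea = include_ea)
      for (stat in names(ranked)) for (k in k_values)
        rows[[length(rows) + 1L]] <- data.frame(
          delta = delta, statistic = stat, k = k, trial = trial,
          pct = pct_sdg_in_top_k(ranked[[stat]], ds$truth_ids, k))
    }
  }
  per_trial <- do.call(rbind, rows)
  out <- .average_trials(per_trial, c("delta", "statistic", "k"))
  out$trials <- trials
  out$seed <- seed
  attr(out, "per_trial") <- per_trial
  out
}

#' Compare signature-sizing methods: inflection versus q-value
#'
#' For each constant noise level: generate datasets, size a signature two
#' ways — the inflection method applied to the |T_diff| eigengene ranking,
#' and the q-value threshold (`max_q`) applied to the pooled t — and record
#' signature size (SS), planted genes captured (SDG in signature),
#' statistical power SP = captured / planted, and
#' FDR = (SS - captured) / SS (0 for an empty signature). Trial-averaged.
#'
#' @param sigma_grid Noise levels (default `c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0)`).
#' @param delta Planted shift (default 1).
#' @param max_q q-value threshold for the comparator (default 0.05).
#' @param trials Trials per level (default 5).
#' @param seed Base seed.
#' @param config Template [simulation_config()].
#' @return A data.frame with columns `sigma`, `method` (`"inflection"` /
#'   `"qvalue"`), `ss`, `sdg_in_signature`, `sp`, `fdr`, `trials`, `seed`;
#'   per-trial values in `attr(, "per_trial")`.
#' @export
evaluate_signature_methods <- function(sigma_grid = c(0.2, 0.3, 0.4, 0.5,
                                                      0.6, 0.8, 1.0),
                                       delta = 1, max_q = 0.05, trials = 5L,
                                       seed = 0L,
                                       config = simulation_config()) {
  rows <- list()
  for (sigma in sigma_grid) {
    cfg <- simulation_config(m = config$m, n = config$n, n_a = config$n_a,
                             n_b = config$n_b, n_sdg = config$n_sdg,
                             baseline_mean = config$baseline_mean,
                             delta = delta, sigma_regime = "constant",
                             sigma = sigma, trials = trials, seed = seed)
    for (trial in seq_len(trials)) {
      ds <- generate_dataset(cfg, trial)
      z <- standardize(ds$matrix)
      d <- eigengene_decomposition(z, grouping = ds$grouping)
      im <- inflection_cutoff(
        rank_genes(t_diff(eg_group_contributions(z, d, 1L, ds$grouping)),
                   "absolute"))
      qm <- qvalue_cutoff(t_pooled(ds$matrix, ds$grouping), ds$grouping,
                          max_q = max_q)
      for (res in list(list(name = "inflection", s = im),
                       list(name = "qvalue", s = qm))) {
        ss <- res$s$cutoff
        captured <- length(intersect(signature_genes(res$s), ds$truth_ids))
        rows[[length(rows) + 1L]] <- data.frame(
          sigma = sigma, method = res$name, trial = trial, ss = ss,
          sdg_in_signature = captured,
          sp = captured / cfg$n_sdg,
          fdr = if (ss > 0) (ss - captured) / ss else 0)
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  out <- stats::aggregate(per_trial[c("ss", "sdg_in_signature", "sp", "fdr")],
                          per_trial[c("sigma", "method")], mean)
  out$trials <- trials
  out$seed <- seed
  attr(out, "per_trial") <- per_trial
  out
}
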