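#' Simulate a batch of windows under one selection model
#'
#' Runs [run_replicate()] + [measure_replicate()] over a replicate plan
#' (one row per window, tagged with its recombination rate; see
#' [assign_recombination_rates()]), sampling a fresh hotspot map and a
#' fresh window regime for every replicate. Per-replicate seeds are
#' derived deterministically from `seed`, so the batch is reproducible and
#' replicates are independent.
#'
#' @param plan data frame with a `rate` column (cM/Mb), one row per
#'   replicate.
#' @param selection a [selection_model()].
#' @param demography a [demographic_model()].
#' @param layout a [build_layout()] layout.
#' @param mu per-bp mutation rate.
#' @param coverage_law see [measure_replicate()].
#' @param mode see [measure_replicate()].
#' @param seed integer seed for the whole batch.
#' @param n_sample_h,n_sample_c sampled haplotypes per replicate.
#' @param keep_replicates return the raw `sim_replicate` objects as well
#'   (memory permitting).
#' @param purge_every fixation-sweep cadence, in rescaled generations.
#' @param hotspots sample a hotspot map per replicate (default TRUE).
#' @return list with `measurements` (one row per window) and, when
#'   requested, `replicates`.
#' @export
run_model_batch <- function(plan, selection, demography,
                            layout = build_layout(), mu = 2.5e-8,
                            coverage_law = NULL,
                            mode = "population-MAF", seed = 1,
                            n_sample_h = 12, n_sample_c = 2,
                            keep_replicates = FALSE, purge_every = 25,
                            hotspots = TRUE) {
  meas <- vector("list", nrow(plan))
  reps <- if (keep_replicates) vector("list", nrow(plan)) else NULL
  fix_tab <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    seed_i <- (seed * 1009 + i * 7919) %% 2147483629
    set.seed(seed_i)
    hmap <- if (hotspots) {
      sample_hotspot_map(attr(layout, "window_length"))
    } else NULL
    r <- run_replicate(layout, demography, selection, hotspot_map = hmap,
                       rate = plan$rate[i], mu = mu, seed = seed_i,
                       n_sample_h = n_sample_h, n_sample_c = n_sample_c,
                       purge_every = purge_every)
    meas[[i]] <- measure_replicate(r, coverage_law = coverage_law,
                                   mode = mode)
    fx <- r$fixed_h
    fix_tab[[i]] <- data.frame(
      replicate = i,
      n_pos_fix = sum(r$muts$class[match(fx$id, r$muts$id)] ==
                        "nonsynonymous" &
                        r$muts$s[match(fx$id, r$muts$id)] > 0),
      regime = r$regime)
    meas[[i]]$has_recent_pos_fix <- .has_recent_pos_fix(r, 20000)
    if (keep_replicates) reps[[i]] <- r
  }
  out <- list(measurements = do.call(rbind, meas),
              fixations = do.call(rbind, fix_tab))
  if (keep_replicates) out$replicates <- reps
  out
}

.has_recent_pos_fix <- function(r, horizon) {
  fx <- r$fixed_h
  if (nrow(fx) == 0) return(FALSE)
  mm <- match(fx$id, r$muts$id)
  any(r$muts$class[mm] == "nonsynonymous" & r$muts$s[mm] > 0 &
        fx$gen_before_present <= horizon)
}

#' Model-vs-data comparison of window correlations
#'
#' For each selection model, simulates windows across the empirical
#' recombination-rate distribution and computes the Spearman correlations
#' the data pipeline reports -- `S_norm` vs recombination rate, mean MAF vs
#' rate, `S_norm` vs `d_N`, and `d` vs rate -- with percentile bootstrap
#' confidence intervals, for overlay against the observed values.
#'
#' @param plan replicate plan (see [assign_recombination_rates()]).
#' @param models named list of [selection_model()]s.
#' @param demography a [demographic_model()].
#' @param n_boot bootstrap resamples for the CIs.
#' @param ... passed to [run_model_batch()].
#' @param seed integer seed.
#' @return list with `measurements` (all windows, tagged by model) and
#'   `comparison` (one row per model x correlation: `rho`, `ci_low`,
#'   `ci_high`, `n`).
#' @export
simulation_study <- function(plan, models, demography, n_boot = 200,
                             seed = 1, ...) {
  if (length(unique(plan$rate)) < 2) {
    stop_param("the plan must span at least 2 recombination-rate bins")
  }
  all_meas <- NULL
  comp <- NULL
  pairs <- list(c("S_norm", "rate"), c("mean_maf", "rate"),
                c("S_norm", "d_N"), c("d", "rate"))
  for (mi in seq_along(models)) {
    nm <- names(models)[mi]
    batch <- run_model_batch(plan, models[[mi]], demography,
                             seed = seed + 104729 * mi, ...)
    m <- batch$measurements
    m$model <- nm
    all_meas <- rbind(all_meas, m)
    ok <- m[!m$excluded, , drop = FALSE]
    for (pr in pairs) {
      x <- ok[[pr[1]]]
      y <- ok[[pr[2]]]
      cc <- stats::complete.cases(x, y)
      rho <- if (sum(cc) >= 3 && length(unique(y[cc])) > 1 &&
                   length(unique(x[cc])) > 1) {
        spearman_cor(x[cc], y[cc])$rho
      } else NA_real_
      ci <- c(NA_real_, NA_real_)
      if (!is.na(rho) && sum(cc) >= 30) {
        dat <- data.frame(x = x[cc], y = y[cc])
        ci <- bootstrap_ci(dat, function(d) {
          if (length(unique(d$x)) < 2 || length(unique(d$y)) < 2) {
            return(NA_real_)
          }
          cor(rank(d$x), rank(d$y))
        }, n_boot = n_boot, seed = seed + mi)
      }
      comp <- rbind(comp, data.frame(
        model = nm, statistic = paste(pr[1], "vs", pr[2]), rho = rho,
        ci_low = ci[1], ci_high = ci[2], n = sum(cc)))
    }
  }
  list(measurements = all_meas, comparison = comp)
}
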