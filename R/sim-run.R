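#' Run one forward Wright-Fisher window replicate
#'
#' Simulates one window under the given layout, demography, selection
#' model and recombination map, and returns the sampled outcome: a human
#' population sample, one chimp individual, per-mutation annotation,
#' per-population fixation records, and exact mutation bookkeeping. The
#' engine burns the ancestral population in for `burn_factor * 2 N`
#' (rescaled) generations, splits it into the two descendant populations,
#' and simulates both to the present; fitness is multiplicative across
#' sites with dominance `h`, and all rates are rescaled internally by the
#' demography's `lambda`.
#'
#' @param layout a [build_layout()] window layout.
#' @param demography a [demographic_model()].
#' @param selection a [selection_model()].
#' @param hotspot_map a [sample_hotspot_map()] result, or `NULL` for a
#'   uniform map.
#' @param rate sex-averaged recombination rate in cM/Mb.
#' @param mu per-bp per-generation mutation rate (default 2.5e-8,
#'   Jukes-Cantor symmetric).
#' @param seed integer seed; drives both the window-regime draw and the
#'   engine's generator, so a replicate is fully reproducible from
#'   `(inputs, seed)` alone.
#' @param regime force the window regime (`"neutral"`, `"negative"`,
#'   `"positive"`); `NULL` draws it from the model's `p_plus` / `p_minus`.
#' @param n_sample_h,n_sample_c numbers of sampled haplotypes (whole
#'   individuals; defaults 12 and 2).
#' @param purge_every generations between fixation sweeps of the
#'   population (bounds the resolution of fixation times).
#' @param no_demography `TRUE` runs burn-in only and samples the ancestral
#'   population (equilibrium calibration mode; no chimp lineage).
#' @return list of class `sim_replicate`: `muts` (data frame `id`, `pos`,
#'   `class` in `intergenic`/`intron`/`synonymous`/`nonsynonymous`, `s`,
#'   unrescaled), `freq_h` / `freq_c` (`id`, `count` per population),
#'   `two_N_h`, `sample_h`,
#'   `sample_c` (lists of 0-based mutation-id vectors, consecutive pairs =
#'   one individual), `fixed_h`, `fixed_c`, `fixed_anc` (data frames with
#'   `id`, `gen_before_present` in unrescaled generations), `bookkeeping`,
#'   `layout`, `hotspot_map`, `rate`, `regime`, `seed`, `lambda`.
#' @export
run_replicate <- function(layout, demography, selection,
                          hotspot_map = NULL, rate, mu = 2.5e-8, seed = 1,
                          regime = NULL, n_sample_h = 12, n_sample_c = 2,
                          purge_every = 25, no_demography = FALSE) {
  stopifnot(inherits(demography, "demographic_model"),
            inherits(selection, "selection_model"))
  set.seed(seed)
  if (is.null(regime)) regime <- .draw_regime(selection)
  lam <- demography$lambda
  L <- attr(layout, "window_length")

  if (is.null(hotspot_map)) {
    seg <- data.frame(start = 0, end = L, is_hotspot = FALSE, mass = 1)
  } else {
    seg <- hotspot_map$segments
  }
  seg_cum <- cumsum(seg$mass)
  seg_cum[length(seg_cum)] <- 1  # guard against rounding

  type_code <- c(intergenic = 0L, intron = 1L, exon = 2L)
  N_anc <- max(2L, round(demography$N_anc / lam))
  N_h <- max(2L, round(demography$N_h / lam))
  N_c <- max(2L, round(demography$N_c / lam))
  t_burn <- round(demography$burn_factor * 2 * N_anc)
  t_split <- if (no_demography) 0L else round(demography$t_split / lam)
  bn <- demography$bottleneck
  bn_N <- if (is.null(bn)) 0L else max(2L, round(bn$N / lam))
  bn_start <- if (is.null(bn)) 0L else round(bn$t_start / lam)
  bn_end <- if (is.null(bn)) 0L else round(bn$t_end / lam)

  window_positive <- regime == "positive" && selection$pos_fraction > 0
  use_gamma <- regime == "negative" && selection$dfe_mean > 0
  intron_frac <- if (regime == "negative") selection$intron_del_fraction else 0

  res <- .wf_simulate(
    L = L,
    feat_start = layout$start, feat_end = layout$end,
    feat_type = type_code[layout$type], exon_cum = as.integer(layout$exon_cum),
    seg_start = seg$start, seg_end = seg$end, seg_cum = seg_cum,
    morgans = rate * (L / 1e6) / 100 * lam,
    mu_total = mu * lam * L,
    window_positive = window_positive,
    pos_fraction = selection$pos_fraction,
    s_pos = selection$s_pos * lam,
    use_gamma = use_gamma,
    gamma_shape = selection$dfe_shape,
    gamma_mean = selection$dfe_mean * lam,
    intron_frac = intron_frac,
    s_intron = selection$s_intron * lam,
    h = selection$h,
    N_anc = N_anc, N_h = N_h, N_c = N_c,
    t_burn = t_burn, t_split = t_split,
    bn_N = bn_N, bn_start = bn_start, bn_end = bn_end,
    n_sample_h = n_sample_h, n_sample_c = n_sample_c,
    purge_every = purge_every,
    seed = as.double(seed) %% 2^31)

  class_names <- c("intergenic", "intron", "synonymous", "nonsynonymous")
  # keep only mutations referenced by the outputs (the registry also
  # holds every mutation that was lost along the way)
  ref <- sort(unique(c(res$freq_h$id, res$freq_c$id,
                       unlist(res$sample_h), unlist(res$sample_c),
                       res$fixed_h$id, res$fixed_c$id, res$fixed_anc$id)))
  muts <- data.frame(id = as.integer(ref),
                     pos = res$mut$pos[ref + 1L],
                     class = class_names[res$mut$class[ref + 1L] + 1L],
                     s = res$mut$s[ref + 1L] / lam)
  fix_df <- function(fx) {
    data.frame(id = fx$id, gen_before_present = fx$gen_before_present * lam)
  }
  structure(list(
    muts = muts,
    freq_h = data.frame(id = res$freq_h$id, count = res$freq_h$count),
    freq_c = data.frame(id = res$freq_c$id, count = res$freq_c$count),
    two_N_h = res$two_N_h,
    sample_h = res$sample_h,
    sample_c = res$sample_c,
    fixed_h = fix_df(res$fixed_h),
    fixed_c = fix_df(res$fixed_c),
    fixed_anc = fix_df(res$fixed_anc),
    bookkeeping = res$bookkeeping,
    layout = layout, hotspot_map = hotspot_map, rate = rate,
    regime = regime, seed = seed, lambda = lam,
    demography = demography, selection = selection
  ), class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf(paste0("simulated window: rate %.3g cM/Mb, regime %s, ",
                     "%d segregating (human), %d + %d fixations (H/C)\n"),
              x$rate, x$regime, nrow(x$freq_h), nrow(x$fixed_h),
              nrow(x$fixed_c)))
  invisible(x)
}
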