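#' Two-species demographic model with rescaling
#'
#' An ancestral population of `N_anc` diploids splits `t_split` generations
#' ago into two descendant species, each instantaneously contracted to half
#' the ancestral size by default (human and chimp lineages). The focal
#' (human) lineage can additionally pass through a recent bottleneck.
#' For computational efficiency the simulation is run rescaled by `lambda`:
#' population sizes and times are divided by `lambda` while mutation and
#' recombination rates and selection coefficients are multiplied by it, so
#' all population-scaled parameters (theta, rho, 2Ns) are preserved.
#'
#' @param N_anc ancestral diploid size (default 20000).
#' @param N_h,N_c descendant diploid sizes (default 10000 each: a 2-fold
#'   contraction at the split).
#' @param t_split generations before present of the species split
#'   (default 200000, i.e. 5 Myr at 25 years/generation).
#' @param bottleneck `NULL`, or a list `list(N =, t_start =, t_end =)` in
#'   unrescaled diploids / generations before present. The shipped default
#'   (`default_bottleneck()`) is a placeholder out-of-Africa-style
#'   contraction to `N_h / 10` lasting 500 generations and ending 1000
#'   generations ago; real analyses should set their own.
#' @param lambda rescaling factor (default 40: the ancestral population is
#'   simulated with 500 diploids).
#' @param burn_factor burn-in length in units of `2 N_anc` (rescaled)
#'   generations before the split (default 10).
#' @return list of class `demographic_model`.
#' @export
demographic_model <- function(N_anc = 20000, N_h = 10000, N_c = 10000,
                              t_split = 200000,
                              bottleneck = default_bottleneck(),
                              lambda = 40, burn_factor = 10) {
  if (min(N_anc, N_h, N_c) / lambda < 2) {
    stop_param("rescaled population sizes must be >= 2 diploids")
  }
  if (!is.null(bottleneck)) {
    if (bottleneck$t_start <= bottleneck$t_end || bottleneck$t_end < 0 ||
        bottleneck$t_start >= t_split) {
      stop_param("bottleneck times must satisfy t_split > t_start > t_end >= 0")
    }
  }
  structure(list(N_anc = N_anc, N_h = N_h, N_c = N_c, t_split = t_split,
                 bottleneck = bottleneck, lambda = lambda,
                 burn_factor = burn_factor),
            class = "demographic_model")
}

#' @rdname demographic_model
#' @export
default_bottleneck <- function() {
  list(N = 1000, t_start = 1500, t_end = 1000)
}

#' Selection models for simulated windows
#'
#' A `selection_model` describes what happens inside one class of windows
#' and how windows are mixed: with probability `p_plus` a window is a
#' "positive" window where a fraction `pos_fraction` of nonsynonymous
#' mutations are beneficial with coefficient `s_pos` (the remaining
#' nonsynonymous mutations in such windows evolve neutrally); with
#' probability `p_minus` it is a "negative" window where nonsynonymous
#' mutations draw deleterious effects from a gamma distribution (shape
#' `dfe_shape`, mean `dfe_mean`) and a fraction `intron_del_fraction` of
#' intronic mutations are deleterious with coefficient `s_intron`; with
#' the remaining probability the window is entirely neutral. All
#' selection coefficients are unrescaled; dominance is `h` (additive by
#' default).
#'
#' Presets: `model_neutral()` (no selection), `model_bgs_nonsyn()`
#' (gamma-DFE nonsynonymous background selection in every window),
#' `model_bgs_intronic()` (adds weak selection on 25% of intronic sites,
#' s = 2.5e-4, the intermediate strength that maximizes the
#' frequency-spectrum effect), `model_sweep()` (every window can sweep:
#' 0.5% of nonsynonymous mutations beneficial at s = 0.625%, no negative
#' selection), and `model_mixed()` (5% positive windows / 95% negative
#' windows with a gamma DFE plus 50% of intronic sites at s = 7.5e-5).
#'
#' @param dfe_shape,dfe_mean gamma DFE of deleterious nonsynonymous
#'   effects (defaults 0.184 and 0.03; external-source placeholder values,
#'   fully configurable).
#' @param pos_fraction fraction of nonsynonymous mutations beneficial in
#'   positive windows.
#' @param s_pos beneficial selection coefficient.
#' @param intron_del_fraction fraction of intronic mutations deleterious
#'   in negative windows.
#' @param s_intron intronic deleterious coefficient (magnitude).
#' @param p_plus,p_minus window mixture proportions (`p_plus + p_minus <=
#'   1`; remainder neutral).
#' @param h dominance coefficient (default 0.5).
#' @return list of class `selection_model`.
#' @export
selection_model <- function(dfe_shape = 0.184, dfe_mean = 0.03,
                            pos_fraction = 0, s_pos = 0,
                            intron_del_fraction = 0, s_intron = 0,
                            p_plus = 0, p_minus = 0, h = 0.5) {
  if (p_plus < 0 || p_minus < 0 || p_plus + p_minus > 1 + 1e-12) {
    stop_param("need p_plus, p_minus >= 0 and p_plus + p_minus <= 1")
  }
  for (f in c(pos_fraction, intron_del_fraction)) {
    if (f < 0 || f > 1) stop_param("fractions must lie in [0, 1]")
  }
  structure(list(dfe_shape = dfe_shape, dfe_mean = dfe_mean,
                 pos_fraction = pos_fraction, s_pos = s_pos,
                 intron_del_fraction = intron_del_fraction,
                 s_intron = s_intron, p_plus = p_plus, p_minus = p_minus,
                 h = h),
            class = "selection_model")
}

#' @rdname selection_model
#' @export
model_neutral <- function() selection_model()

#' @rdname selection_model
#' @export
model_bgs_nonsyn <- function() selection_model(p_minus = 1)

#' @rdname selection_model
#' @export
model_bgs_intronic <- function(intron_del_fraction = 0.25,
                               s_intron = 2.5e-4) {
  selection_model(p_minus = 1, intron_del_fraction = intron_del_fraction,
                  s_intron = s_intron)
}

#' @rdname selection_model
#' @export
model_sweep <- function(p_plus = 1, pos_fraction = 0.005, s_pos = 0.00625) {
  selection_model(p_plus = p_plus, pos_fraction = pos_fraction,
                  s_pos = s_pos)
}

#' @rdname selection_model
#' @export
model_mixed <- function(p_plus = 0.05, p_minus = 0.95,
                        pos_fraction = 0.005, s_pos = 0.00625,
                        intron_del_fraction = 0.5, s_intron = 7.5e-5) {
  selection_model(p_plus = p_plus, p_minus = p_minus,
                  pos_fraction = pos_fraction, s_pos = s_pos,
                  intron_del_fraction = intron_del_fraction,
                  s_intron = s_intron)
}

# draw the regime of one window under a selection model
.draw_regime <- function(model) {
  u <- runif(1)
  if (u < model$p_plus) "positive"
  else if (u < model$p_plus + model$p_minus) "negative"
  else "neutral"
}
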