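# Small demographies for fast engine checks: population-scaled parameters
# are realistic but absolute sizes are tiny, so a replicate takes
# milliseconds instead of seconds.
small_demography <- function(lambda = 40, N_anc = 4000, t_split = 20000) {
  demographic_model(N_anc = N_anc, N_h = N_anc / 2, N_c = N_anc / 2,
                    t_split = t_split, bottleneck = NULL, lambda = lambda)
}

# a hand-built sim_replicate with planted mutations, for exact checks of
# the measurement step (default 100 kb layout: intergenic block is
# [23500, 76500))
fake_replicate <- function() {
  lay <- build_layout()
  muts <- data.frame(
    id = 0:4,
    pos = c(30000, 30010, 40000, 10, 100.5),
    class = c("intergenic", "intergenic", "intergenic", "exon_pos_na",
              "nonsynonymous"),
    s = c(0, 0, 0, 0, 0.00625))
  muts$class[4] <- "intergenic"   # outside the central block
  structure(list(
    muts = muts,
    freq_h = data.frame(id = c(0L, 1L, 2L, 3L),
                        count = c(10L, 1L, 6L, 10L)),
    two_N_h = 20L,
    sample_h = list(c(0L), integer(0)),
    sample_c = list(integer(0), integer(0)),
    fixed_h = data.frame(id = 4L, gen_before_present = 1000),
    fixed_c = data.frame(id = integer(0),
                         gen_before_present = numeric(0)),
    fixed_anc = data.frame(id = integer(0),
                           gen_before_present = numeric(0)),
    bookkeeping = list(),
    layout = lay, hotspot_map = NULL, rate = 1, regime = "positive",
    seed = 1, lambda = 40
  ), class = "sim_replicate")
}
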