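test_that("window layout has the canonical gene-in-window geometry", {
  lay <- build_layout()
  expect_equal(sum(lay$end - lay$start), 100000)
  expect_equal(attr(lay, "window_length"), 100000)
  expect_equal(sum(lay$type == "exon"), 8)
  expect_equal(sum((lay$end - lay$start)[lay$type == "exon"]), 8 * 1500)
  expect_equal(sum((lay$end - lay$start)[lay$type == "intron"]), 7 * 5000)
  block <- lay[lay$type == "intergenic", ]
  expect_equal(block$end - block$start, 53000)
  # central block is centered: equal arms either side
  expect_equal(block$start, (100000 - 53000) / 2)
  # reading frame is contiguous across exons
  ex <- lay[lay$type == "exon", ]
  expect_equal(ex$exon_cum, cumsum(c(0, rep(1500, 7))))

  lay2 <- build_layout(list(n_exons = 4, n_introns = 3, exon_length = 900,
                            intron_length = 2000, intergenic_length = 10400))
  expect_equal(sum(lay2$end - lay2$start), 4 * 900 + 3 * 2000 + 10400)
  expect_error(build_layout(list(n_exons = 8, n_introns = 5)),
               "n_introns")
  expect_error(build_layout(list(exon_length = 1501)), "multiple of 3")
})

test_that("hotspot maps concentrate exactly 80% of the map in hotspots", {
  for (seed in 1:25) {
    m <- sample_hotspot_map(1e5, seed = seed)
    seg <- m$segments
    expect_equal(sum(seg$mass), 1, tolerance = 1e-12)
    if (m$n_hotspots > 0) {
      expect_equal(sum(seg$mass[seg$is_hotspot]), 0.8, tolerance = 1e-12)
      expect_true(all(abs(seg$end[seg$is_hotspot] -
                            seg$start[seg$is_hotspot] - 2000) < 1e-6))
    }
    # segments tile the window without overlap
    sseg <- seg[order(seg$start), ]
    expect_equal(sseg$start[1], 0)
    expect_equal(sseg$end[nrow(sseg)], 1e5)
    expect_true(all(abs(sseg$start[-1] - sseg$end[-nrow(sseg)]) < 1e-9))
  }
  expect_error(sample_hotspot_map(1000, width = 2000), "shorter")
})

test_that("replicate plans follow the empirical rate distribution", {
  set.seed(1)
  plan <- assign_recombination_rates(runif(5000), n_bins = 100,
                                     n_total = 20000)
  expect_equal(nrow(plan), 20000)
  # uniform rates: every bin gets close to 200 replicates
  occ <- attr(plan, "bins")$n_replicates
  expect_true(all(abs(occ - 200) < 120))
  expect_equal(sum(occ), 20000)

  plan1 <- assign_recombination_rates(rep(2.5, 50), n_total = 77)
  expect_equal(unique(plan1$rate), 2.5)
  expect_equal(nrow(plan1), 77)

  expect_equal(nrow(assign_recombination_rates(runif(10), n_total = 0)), 0)
  expect_error(assign_recombination_rates(c(-1, 1), n_total = 5),
               "non-negative")
})

test_that("half-difference divergence rule handles all genotype cases", {
  expect_equal(half_difference(2, 0), 1)    # opposite homozygotes
  expect_equal(half_difference(0, 2), 1)
  expect_equal(half_difference(0, 0), 0)    # same homozygote
  expect_equal(half_difference(2, 2), 0)
  expect_equal(half_difference(1, 0), 0.5)  # any heterozygote
  expect_equal(half_difference(0, 1), 0.5)
  expect_equal(half_difference(1, 1), 0.5)
  expect_equal(half_difference(1, 2), 0.5)
})

test_that("the engine is deterministic and keeps exact books", {
  dem <- small_demography()
  lay <- build_layout()
  hm <- sample_hotspot_map(1e5, seed = 4)
  r1 <- run_replicate(lay, dem, model_bgs_intronic(), hm, rate = 1,
                      seed = 42, regime = "negative")
  r2 <- run_replicate(lay, dem, model_bgs_intronic(), hm, rate = 1,
                      seed = 42, regime = "negative")
  expect_identical(r1$muts, r2$muts)
  expect_identical(r1$freq_h, r2$freq_h)
  expect_identical(r1$fixed_h, r2$fixed_h)
  expect_identical(lapply(r1$sample_h, identity),
                   lapply(r2$sample_h, identity))

  # frequency accounting: segregating counts strictly inside (0, 2N)
  expect_true(all(r1$freq_h$count >= 1 & r1$freq_h$count < r1$two_N_h))
  # fixed and segregating sets are disjoint within the population
  expect_length(intersect(r1$fixed_h$id, r1$freq_h$id), 0)
  # sampled haplotypes only carry segregating mutations
  expect_true(all(unlist(r1$sample_h) %in% r1$freq_h$id))
  # every reported id is annotated in the mutation table
  expect_true(all(c(r1$freq_h$id, r1$fixed_h$id, r1$fixed_c$id,
                    r1$fixed_anc$id) %in% r1$muts$id))
  bk <- r1$bookkeeping
  expect_equal(bk$n_seg_h, nrow(r1$freq_h))
  expect_gte(bk$n_generated,
             bk$n_fixed_anc + bk$n_fixed_h + bk$n_lost_h + bk$n_seg_h)

  # mutation classes agree with the layout geometry
  block <- r1$layout[r1$layout$type == "intergenic", ]
  ig <- r1$muts$class == "intergenic"
  in_block <- r1$muts$pos >= block$start & r1$muts$pos < block$end
  expect_true(all(ig[in_block]))
  ex <- r1$layout[r1$layout$type == "exon", ]
  in_exon <- rowSums(sapply(seq_len(nrow(ex)), function(i) {
    r1$muts$pos >= ex$start[i] & r1$muts$pos < ex$end[i]
  })) > 0
  expect_true(all(r1$muts$class[in_exon] %in%
                    c("synonymous", "nonsynonymous")))
  # selection only on the designated classes
  expect_true(all(r1$muts$s[r1$muts$class %in%
                              c("intergenic", "synonymous")] == 0))
  # under neutrality (no class-dependent purging) about one third of
  # segregating exonic mutations sit at third (synonymous) positions
  rn <- run_replicate(lay, small_demography(), model_neutral(), NULL,
                      rate = 1, seed = 77)
  ex_cls <- rn$muts$class[rn$muts$class %in%
                            c("synonymous", "nonsynonymous")]
  expect_lt(abs(mean(ex_cls == "synonymous") - 1 / 3), 0.06)
})

test_that("background selection lowers linked neutral diversity (paired)", {
  # full-size population at a stronger rescaling: background selection
  # strength rides on 2 N s, so the population-scaled parameters must be
  # the real ones; at zero recombination the whole window is one linked
  # block and the purging effect is strongest
  dem <- demographic_model(lambda = 80, bottleneck = NULL)
  lay <- build_layout()
  pairs <- vapply(1:40, function(i) {
    rn <- run_replicate(lay, dem, model_neutral(), NULL, rate = 0,
                        seed = 2000 + i, no_demography = TRUE)
    rb <- run_replicate(lay, dem, model_bgs_intronic(), NULL, rate = 0,
                        seed = 2000 + i, regime = "negative",
                        no_demography = TRUE)
    c(measure_replicate(rn, seed = 1)$pi,
      measure_replicate(rb, seed = 1)$pi)
  }, numeric(2))
  expect_lt(mean(pairs[2, ]), mean(pairs[1, ]))
  wins <- sum(pairs[2, ] < pairs[1, ])
  expect_lt(binom.test(wins, 40, alternative = "greater")$p.value, 0.01)
})

test_that("deleterious mutations segregate at lower frequencies", {
  dem <- demographic_model(N_anc = 2000, N_h = 1000, N_c = 1000,
                           t_split = 10000, bottleneck = NULL, lambda = 40)
  lay <- build_layout()
  sel_f <- neu_f <- NULL
  for (i in 1:25) {
    r <- run_replicate(lay, dem, model_bgs_intronic(s_intron = 1e-3), NULL,
                       rate = 1, seed = 3000 + i, regime = "negative",
                       no_demography = TRUE)
    fr <- merge(r$freq_h, r$muts, by = "id")
    sel_f <- c(sel_f, fr$count[fr$s < 0] / r$two_N_h)
    neu_f <- c(neu_f, fr$count[fr$class == "intergenic"] / r$two_N_h)
  }
  expect_gt(length(sel_f), 100)
  expect_lt(mean(sel_f), mean(neu_f))
})

test_that("rescaled runs are statistically indistinguishable", {
  lay <- build_layout()
  S_of <- function(lambda, seeds) {
    dem <- small_demography(lambda = lambda)
    vapply(seeds, function(s) {
      r <- run_replicate(lay, dem, model_neutral(), NULL, rate = 1.2,
                         seed = s)
      measure_replicate(r, mode = "sample-6", seed = 1)$S
    }, numeric(1))
  }
  s40 <- S_of(40, 4000 + 1:70)
  s80 <- S_of(80, 5000 + 1:70)
  expect_gt(suppressWarnings(stats::ks.test(s40, s80)$p.value), 0.01)
})

test_that("recent beneficial fixations increase with the positive fraction", {
  lay <- build_layout()
  dem <- small_demography(lambda = 40, N_anc = 4000, t_split = 20000)
  frac_of <- function(p_plus, seeds) {
    reps <- lapply(seeds, function(s) {
      run_replicate(lay, dem, model_sweep(p_plus = p_plus), NULL,
                    rate = 1, seed = s)
    })
    sweep_fixation_fraction(reps, horizon = 20000)
  }
  f100 <- frac_of(1, 6000 + 1:30)
  f5 <- frac_of(0.05, 6100 + 1:30)
  expect_gte(f100, f5)
  expect_gt(f100, 0)
  # no positive selection at all: never a beneficial fixation
  reps0 <- lapply(1:8, function(s) {
    run_replicate(lay, dem, model_neutral(), NULL, rate = 1, seed = s)
  })
  expect_equal(sweep_fixation_fraction(reps0), 0)
})

test_that("replicate measurement recovers planted quantities exactly", {
  fake <- fake_replicate()
  m <- measure_replicate(fake, mode = "population-MAF", seed = 9)
  # MAF > 5% filter: ids 0 (p=.5) and 2 (p=.3) pass; id 1 (p=.05) is
  # excluded by the strict threshold; id 3 lies outside the block
  expect_equal(m$S, 2)
  expect_equal(m$mean_maf, mean(c(0.5, 0.3)))
  expect_equal(m$covered, 53000)
  # divergence: human individual is het for id 0 (0.5) and hom for the
  # fixed nonsynonymous id 4 (excluded from intergenic d)
  expect_equal(m$d, 0.5)
  expect_equal(m$S_norm, 2 / 0.5)
  expect_equal(m$d_N, 1 / (12000 * 2 / 3))
  expect_equal(m$d_S, 0)
  # pi: sum of 2 p (1-p) 2N/(2N-1) over the three in-block sites
  p <- c(0.5, 0.05, 0.3)
  expect_equal(m$pi, sum(2 * p * (1 - p)) * 20 / 19)

  m6 <- measure_replicate(fake, mode = "sample-6", seed = 9)
  expect_equal(m6$S, 1)              # only id 0 segregates in the sample
  expect_equal(m6$mean_maf, 0.5)

  # coverage law restricts the analyzed stretch
  m_cov <- measure_replicate(fake, coverage_law = 10000, seed = 1)
  expect_equal(m_cov$covered, 10000)
})

test_that("YAML configs construct the simulation objects", {
  skip_if_not_installed("yaml")
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "demography:",
    "  N_anc: 8000",
    "  N_h: 4000",
    "  N_c: 4000",
    "  t_split: 40000",
    "  lambda: 40",
    "  bottleneck: null",
    "selection:",
    "  p_minus: 1",
    "  intron_del_fraction: 0.25",
    "  s_intron: 2.5e-4",
    "layout:",
    "  intergenic_length: 53000"), cfg)
  sim <- read_sim_config(cfg)
  expect_equal(sim$demography$N_anc, 8000)
  expect_null(sim$demography$bottleneck)
  expect_equal(sim$selection$s_intron, 2.5e-4)
  expect_equal(attr(sim$layout, "window_length"), 1e5)
})

test_that("a small simulation study produces the comparison table", {
  plan <- data.frame(replicate = 1:8, rate = rep(c(0.2, 2), each = 4))
  dem <- small_demography()
  out <- simulation_study(plan,
                          list(neutral = model_neutral()),
                          dem, n_boot = 0, seed = 3, purge_every = 50)
  expect_equal(nrow(out$measurements), 8)
  expect_equal(nrow(out$comparison), 4)
  expect_true(all(c("rho", "ci_low", "ci_high") %in%
                    names(out$comparison)))
  expect_error(simulation_study(data.frame(rate = rep(1, 5)),
                                list(n = model_neutral()), dem),
               "2 recombination-rate bins")
})
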