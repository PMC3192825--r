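test_that("genome partitioning tiles and excludes near trouble spots", {
  # 25 Mb chromosome, default 10 Mb end exclusions: windows in [10, 15) Mb
  w <- partition_genome(data.frame(chrom = "chr1", length = 25e6))
  expect_equal(nrow(w), 50)
  expect_equal(min(w$start), 10e6)
  expect_equal(max(w$end), 15e6)

  # exclusions cover everything
  expect_equal(nrow(partition_genome(data.frame(chrom = "chr1",
                                                length = 20e6))), 0)

  # trailing partial window dropped
  w2 <- partition_genome(data.frame(chrom = "chr1", length = 25e6 + 50001),
                         window_size = 1e5)
  expect_true(all((w2$end - w2$start) == 1e5))
  expect_lte(max(w2$end), 25e6 + 50001 - 10e6)

  # centromere annotation carves out its buffered zone
  cen <- data.frame(chrom = "chr1", start = 30e6, end = 31e6)
  w3 <- partition_genome(data.frame(chrom = "chr1", length = 60e6), cen)
  expect_false(any(w3$start < 41e6 & w3$end > 20e6))

  expect_error(
    partition_genome(data.frame(chrom = "chr1", length = 50e6),
                     data.frame(chrom = "chr1", start = -5, end = 10)),
    "line 1")
})

test_that("variant ingestion applies the neutral-site filters", {
  v <- data.frame(
    chrom = "chr1",
    pos = c(100, 200, 300, 301, 400, 500, 600, 602, 700),
    ref = c("A", "A", "A", "AT", "G", "C", "A", "A", "T"),
    alt = c("G", "G,T", "G", "A", "A", "T", "C", "G", "A"))
  masks <- list(
    repeats = data.frame(chrom = "chr1", start = 395, end = 405),
    conserved = data.frame(chrom = "chr1", start = 495, end = 505))
  out <- ingest_variants(v, masks)
  # kept: 100 (clean), 602 (2 bp from indel at 300? no -- indel at 301)
  # dropped: 200 triallelic, 300 (1 bp from indel), 301 indel itself,
  #          400 repeat-masked, 500 conserved
  expect_true(100 %in% out$pos)
  expect_true(700 %in% out$pos)
  expect_false(any(c(200, 300, 301, 400, 500) %in% out$pos))
  # 600 is 1 bp from no indel (indel at 301): distance 299, retained
  expect_true(600 %in% out$pos)

  # boundary: 1 bp from an indel removed, exactly 2 bp away retained
  v2 <- data.frame(chrom = "chr1", pos = c(10, 49, 50, 52),
                   ref = c("A", "A", "AT", "G"),
                   alt = c("C", "C", "A", "T"))
  out2 <- ingest_variants(v2, NULL)
  expect_false(49 %in% out2$pos)
  expect_true(52 %in% out2$pos)
  expect_true(10 %in% out2$pos)

  # observed alleles not matching the reference are removed
  v3 <- data.frame(chrom = "chr1", pos = c(5, 6), ref = c("A", "C"),
                   alt = c("G", "T"), alleles = c("G,T", "C,T"))
  out3 <- ingest_variants(v3, NULL)
  expect_equal(out3$pos, 6)

  expect_error(
    ingest_variants(data.frame(chrom = "chr1", pos = c(5, 2),
                               ref = "A", alt = "C"), NULL),
    "sorted")
})

test_that("VCF import produces ingestible 0-based records", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tA\tG\t50\tPASS\t.",
    "chr1\t205\t.\tC\tT,A\t50\tPASS\t.",
    "chr1\t300\t.\tGA\tG\t50\tPASS\t."), vcf)
  v <- read_variants_vcf(vcf)
  expect_equal(v$pos, c(100, 204, 299))
  out <- ingest_variants(v, NULL)
  expect_equal(out$pos, 100)  # multiallelic and indel records removed
})

test_that("window summaries compute the normalized diversity measure", {
  win <- list(chrom = "chr1", start = 0, end = 1e5)
  masks <- list(coverage = data.frame(chrom = "chr1", start = 0, end = 5000),
                aligned = data.frame(chrom = "chr1", start = 0, end = 5000),
                repeats = NULL, conserved = NULL)
  snps <- data.frame(chrom = "chr1", pos = seq(10, 1000, length.out = 10),
                     maf = rep(0.2, 10))
  hc <- data.frame(chrom = "chr1", pos = seq(5, 4900, length.out = 50))
  s <- summarize_window(win, snps, masks, hc)
  expect_equal(s$S, 10)
  expect_equal(s$covered, 5000)
  expect_equal(s$d, 50)
  expect_equal(s$S_norm, (10 / 5000) / (50 / 5000))  # = 0.2
  expect_equal(s$mean_maf, 0.2)
  expect_false(s$excluded)

  # the literal raw-count denominator is available as a flag
  s_raw <- summarize_window(win, snps, masks, hc, normalize_aligned = FALSE)
  expect_equal(s_raw$S_norm, (10 / 5000) / 50)

  # no SNPs: S_norm 0, mean MAF undefined
  s0 <- summarize_window(win, snps[0, ], masks, hc)
  expect_equal(s0$S_norm, 0)
  expect_true(is.na(s0$mean_maf))

  # fully masked window: counts zero, flagged for exclusion
  masked <- list(coverage = data.frame(chrom = "chr1", start = 0, end = 0),
                 aligned = NULL, repeats = NULL, conserved = NULL)
  sm <- summarize_window(win, snps[0, ], masked, hc[0, ])
  expect_equal(sm$covered, 0)
  expect_true(sm$excluded)
})

test_that("covered-base accounting is conserved over disjoint sub-windows", {
  set.seed(8)
  m <- gen_masks(list(chrom = "chr1", start = 0, end = 1e5), 0.4, 0.06,
                 covered_frac = 0.8, seed = 8)
  masks <- list(coverage = m$coverage, repeats = m$repeats,
                conserved = m$conserved, aligned = NULL)
  whole <- summarize_window(list(chrom = "chr1", start = 0, end = 1e5),
                            NULL, masks, NULL)
  parts <- lapply(seq(0, 9e4, by = 1e4), function(a) {
    summarize_window(list(chrom = "chr1", start = a, end = a + 1e4),
                     NULL, masks, NULL)
  })
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "covered")),
               whole$covered)
})

test_that("summaries are invariant to input row order", {
  set.seed(9)
  snps <- data.frame(chrom = "chr1", pos = sample.int(1e5, 200),
                     maf = runif(200, 0.05, 0.5))
  snps <- snps[order(snps$pos), ]
  hc <- data.frame(chrom = "chr1", pos = sample.int(1e5, 500))
  m <- gen_masks(list(chrom = "chr1", start = 0, end = 1e5), 0.3, 0.05,
                 seed = 10)
  masks1 <- list(coverage = NULL, repeats = m$repeats,
                 conserved = m$conserved, aligned = NULL)
  masks2 <- list(coverage = NULL,
                 repeats = m$repeats[sample(nrow(m$repeats)), ],
                 conserved = m$conserved[sample(nrow(m$conserved)), ],
                 aligned = NULL)
  w <- list(chrom = "chr1", start = 0, end = 1e5)
  s1 <- summarize_window(w, snps, masks1, hc)
  s2 <- summarize_window(w, snps, masks2, hc[sample(nrow(hc)), ])
  expect_equal(s1, s2)
})

test_that("Tajima's D matches an independent implementation", {
  expect_equal(tajimas_d(16, 3.888889, 10), oracle_tajima(16, 3.888889, 10),
               tolerance = 1e-10)
  for (n in c(4, 10, 50, 200)) {
    for (S in c(1, 7, 40)) {
      pi <- S / sum(1 / seq_len(n - 1)) * runif(1, 0.5, 2)
      expect_equal(tajimas_d(S, pi, n), oracle_tajima(S, pi, n),
                   tolerance = 1e-10)
    }
  }
  # numerator zero when pi equals Watterson's expectation
  a1 <- sum(1 / seq_len(9))
  expect_equal(tajimas_d(16, 16 / a1, 10), 0, tolerance = 1e-12)
  # an excess of singletons gives negative D
  n <- 40
  S <- 30
  pi_singletons <- S * 2 * (n - 1) / (n * (n - 1))
  expect_lt(tajimas_d(S, pi_singletons, n), 0)
  expect_warning(out <- tajimas_d(0, 0, 10), "undefined")
  expect_true(is.na(out))
})

test_that("heterozygosity outlier filter follows its two-part rule", {
  expect_false(cgs_het_filter(rep(c(3, 4), c(6, 6))))  # 12 SNPs, mean 3.5
  expect_true(cgs_het_filter(rep(6, 9)))               # too few SNPs
  expect_true(cgs_het_filter(rep(3, 15)))              # mean exactly 3
  expect_error(cgs_het_filter(c(1, 7)), "0, 6")
})

test_that("window classes split at zero and half genic content", {
  expect_equal(classify_window(0), "nongenic")
  expect_equal(classify_window(0.5), "genic")
  expect_equal(classify_window(1), "genic")
  expect_equal(classify_window(0.3), "neither")
  expect_error(classify_window(1.2), "genic_frac")
})

test_that("pi from a dosage matrix equals the pairwise-difference formula", {
  g <- rbind(c(0, 1, 2), c(1, 1, 0))  # 2 sites x 3 diploids, n = 6
  k <- rowSums(g)
  expect_equal(pi_from_genotypes(g, 6),
               sum(2 * k * (6 - k) / (6 * 5)))
})
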