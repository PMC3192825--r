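test_that("Spearman correlation is rank-based with average ties", {
  expect_equal(spearman_cor(1:10, 2 * (1:10) + 1)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)

  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  r <- spearman_cor(x, y)
  expect_equal(r$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(r$rho, unname(cor(x, y, method = "spearman")),
               tolerance = 1e-12)

  # invariance to strictly monotone transforms
  set.seed(1)
  a <- rnorm(60)
  b <- rnorm(60)
  expect_equal(spearman_cor(exp(a), b)$rho, spearman_cor(a, b)$rho)
  expect_equal(spearman_cor(a, b^3)$rho,
               spearman_cor(a, b)$rho)

  # incomplete pairs dropped
  expect_equal(spearman_cor(c(a, NA), c(b, 1))$n_windows, 60)
  expect_warning(rc <- spearman_cor(rep(1, 10), 1:10), "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("partial Spearman matches the first-order closed form", {
  # no controls: exact reduction to the pairwise statistic
  set.seed(2)
  x <- rnorm(100)
  y <- rnorm(100)
  expect_equal(partial_spearman(x, y, NULL)$rho, spearman_cor(x, y)$rho)

  # one control: (rxy - rxz ryz) / sqrt((1-rxz^2)(1-ryz^2)) on ranks
  z <- rnorm(100)
  x1 <- x + z
  y1 <- y + 0.5 * z
  rxy <- cor(rank(x1), rank(y1))
  rxz <- cor(rank(x1), rank(z))
  ryz <- cor(rank(y1), rank(z))
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_spearman(x1, y1, cbind(z = z))$rho, closed,
               tolerance = 1e-10)

  # construction: x and y only associated through z
  set.seed(3)
  z2 <- rnorm(5000)
  x2 <- z2 + rnorm(5000)
  y2 <- z2 + rnorm(5000)
  expect_gt(spearman_cor(x2, y2)$rho, 0.3)
  expect_lt(abs(partial_spearman(x2, y2, cbind(z = z2))$rho), 0.05)

  # collinear controls are named in the error
  expect_error(
    partial_spearman(x, y, cbind(z1 = z, z2 = z)),
    "collinear")
})

test_that("partial Spearman with independent controls tracks the pairwise", {
  set.seed(4)
  n <- 5000
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  ctl <- cbind(u = rnorm(n), v = rnorm(n))
  expect_lt(abs(partial_spearman(x, y, ctl)$rho - spearman_cor(x, y)$rho),
            0.02)
})

test_that("genic permutation test has valid null p-values and power", {
  stat <- function(w) cor(rank(w$S_norm), rank(w$rate))

  # null calibration: both groups from one population -> p ~ Uniform(0,1]
  set.seed(5)
  pvals <- replicate(150, {
    w <- data.frame(S_norm = rnorm(80), rate = rnorm(80),
                    class = rep(c("genic", "nongenic"), each = 40))
    genic_permutation_test(w, stat, n_perm = 199,
                           seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # empirical type-I error at or below nominal (within binomial slack)
  expect_lte(mean(pvals <= 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 150))

  # power: a planted correlation difference of ~0.3 is detected
  lat <- 2 * sin(pi * 0.3 / 6)   # latent rho giving Spearman ~0.3
  cop <- diag(2)
  cop[1, 2] <- cop[2, 1] <- lat
  marg <- list(S_norm = list(dist = "norm"), rate = list(dist = "norm"))
  set.seed(6)
  hits <- replicate(25, {
    g <- gen_window_table(500, cop, marg, seed = sample.int(1e6, 1))
    ng <- gen_window_table(500, diag(2), marg, seed = sample.int(1e6, 1))
    w <- rbind(data.frame(g, class = "genic"),
               data.frame(ng, class = "nongenic"))
    genic_permutation_test(w, stat, n_perm = 399,
                           seed = sample.int(1e6, 1))$p_value <= 0.01
  })
  expect_gte(mean(hits), 0.95)

  # conventions and guards
  w <- data.frame(S_norm = rnorm(40), rate = rnorm(40),
                  class = rep(c("genic", "nongenic"), each = 20))
  p1 <- genic_permutation_test(w, stat, n_perm = 99, seed = 1)
  expect_gt(p1$p_value, 0)
  p2 <- genic_permutation_test(w, stat, n_perm = 99, seed = 1,
                               add_one = FALSE)
  expect_equal(p1$p_value, (p2$p_value * 99 + 1) / 100)
  expect_error(genic_permutation_test(w, stat, n_perm = 0), "positive")
  w_small <- data.frame(S_norm = rnorm(12), rate = rnorm(12),
                        class = rep(c("genic", "nongenic"), each = 6))
  expect_warning(genic_permutation_test(w_small, stat, n_perm = 19,
                                        seed = 1), "fewer than 10")
})

test_that("bootstrap intervals behave like percentile intervals should", {
  w <- data.frame(x = rnorm(1000))
  # constant statistic: zero-width interval
  ci0 <- bootstrap_ci(w, function(d) 1, n_boot = 50, seed = 1)
  expect_equal(unname(ci0[1]), unname(ci0[2]))

  # CLT check: CI for a N(0,1) mean at n = 1000
  set.seed(7)
  w2 <- data.frame(x = rnorm(1000))
  ci <- bootstrap_ci(w2, function(d) mean(d$x), n_boot = 600, seed = 2)
  half <- (ci[2] - ci[1]) / 2
  expect_lt(abs(half - 1.96 / sqrt(1000)) / (1.96 / sqrt(1000)), 0.15)

  expect_identical(bootstrap_ci(w2, function(d) mean(d$x), 100, seed = 3),
                   bootstrap_ci(w2, function(d) mean(d$x), 100, seed = 3))

  # undefined statistic on a resample: redrawn and counted
  set.seed(8)
  w3 <- data.frame(x = c(rep(NA, 12), rnorm(30)))
  ci3 <- bootstrap_ci(w3, function(d) {
    if (anyNA(d$x[1:5])) NA_real_ else mean(d$x, na.rm = TRUE)
  }, n_boot = 50, seed = 4)
  expect_gt(attr(ci3, "n_redrawn"), 0)
  expect_error(bootstrap_ci(w2[1:10, , drop = FALSE], mean), "30 windows")
})

test_that("percentile subsetting keeps the top tail", {
  w <- data.frame(d_N = sample(1:100))
  expect_equal(nrow(subset_by_percentile(w, "d_N", 0.90)), 10)
  expect_true(all(subset_by_percentile(w, "d_N", 0.90)$d_N > 90))
  w_eq <- data.frame(d_N = rep(3, 25))
  expect_equal(nrow(subset_by_percentile(w_eq, "d_N", 0.90)), 25)
  expect_equal(nrow(subset_by_percentile(w, "d_N", 0)), 100)
  expect_error(subset_by_percentile(w, "nope"), "not found")
})

test_that("rate-sorted binning averages fixed-size groups", {
  w <- data.frame(chrom = "chr1", start = seq(0, by = 1e5, length.out = 100),
                  rec_rate = runif(100), S_norm = rnorm(100))
  b <- bin_windows(w, "rec_rate", 50)
  expect_equal(nrow(b), 2)
  expect_equal(b$n, c(50, 50))
  expect_false(any(b$partial))
  # bin means equal the means of the sorted halves
  srt <- w[order(w$rec_rate, w$chrom, w$start), ]
  expect_equal(b$S_norm[1], mean(srt$S_norm[1:50]))

  b3 <- bin_windows(rbind(w, w[1, ]), "rec_rate", 50)
  expect_equal(nrow(b3), 3)
  expect_equal(b3$n[3], 1)
  expect_true(b3$partial[3])

  # constant key: ties broken by genomic coordinate, reproducibly
  w_tie <- w
  w_tie$rec_rate <- 1
  expect_identical(bin_windows(w_tie, "rec_rate", 30),
                   bin_windows(w_tie[sample(100), ], "rec_rate", 30))
})
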