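#' Half-difference divergence rule for two diploid genotypes
#'
#' Interspecies divergence measured from one individual of each species:
#' a site where both individuals are homozygous for different alleles
#' counts as 1 difference, a site where both are homozygous for the same
#' allele counts as 0, and every configuration involving a heterozygote
#' counts as half a difference.
#'
#' @param dosage_a,dosage_b derived-allele dosages (0, 1 or 2) for the two
#'   individuals; vectorized.
#' @return numeric vector of per-site difference contributions.
#' @examples
#' half_difference(2, 0)  # 1
#' half_difference(0, 0)  # 0
#' half_difference(1, 0)  # 0.5
#' @export
half_difference <- function(dosage_a, dosage_b) {
  ifelse(dosage_a == 1 | dosage_b == 1, 0.5,
         ifelse(dosage_a == dosage_b, 0, 1))
}

# dosage of each id in a diploid built from two haplotype id-vectors plus a
# set of ids fixed in that individual's population
.dosage <- function(ids, hap1, hap2, fixed_ids) {
  (ids %in% hap1) + (ids %in% hap2) + 2 * (ids %in% fixed_ids)
}

#' Measure a simulated replicate like the data pipeline would
#'
#' Computes the same window summaries as the empirical analysis, restricted
#' to the neutral intergenic sequence: segregating sites `S`, average minor
#' allele frequency, pairwise diversity and Tajima's D, human-chimp
#' divergence `d` from one individual per species under the half-difference
#' rule, and divergence-normalized diversity `S_norm`. Nonsynonymous and
#' synonymous divergence are measured positionally: `d_N` is the per-site
#' rate of human-chimp differences at first and second codon positions,
#' `d_S` at third positions.
#'
#' The amount of intergenic sequence analyzed can be drawn from an
#' empirical coverage distribution (`coverage_law`), mirroring how much of
#' a real window has usable data; the analyzed stretch is a contiguous
#' random sub-block.
#'
#' @param rep a [run_replicate()] result.
#' @param coverage_law `NULL` (analyze the whole intergenic block), a
#'   numeric vector of empirical per-window covered-base counts to resample
#'   from, or a single number of bases.
#' @param mode `"population-MAF"`: `S` counts intergenic SNPs whose
#'   population MAF exceeds `maf_threshold` (low-coverage-style analysis);
#'   `"sample-6"`: all SNPs segregating in the sampled individuals
#'   (small-panel-style), no MAF filter.
#' @param maf_threshold population-MAF cut for `mode = "population-MAF"`
#'   (default 0.05).
#' @param seed optional seed for the coverage draw and sub-block placement.
#' @return one-row data frame: `rate`, `regime`, `S`, `covered`, `d`,
#'   `aligned`, `S_norm`, `mean_maf`, `pi` (per analyzed window), `pi_site`,
#'   `tajimas_D`, `d_N`, `d_S`, `excluded`.
#' @export
measure_replicate <- function(rep, coverage_law = NULL,
                              mode = c("population-MAF", "sample-6"),
                              maf_threshold = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  block <- .intergenic_block(rep$layout)
  block_len <- block$end - block$start
  alen <- if (is.null(coverage_law)) {
    block_len
  } else if (length(coverage_law) > 1) {
    sample(coverage_law, 1)
  } else {
    coverage_law
  }
  alen <- min(alen, block_len)
  a0 <- block$start + runif(1, 0, block_len - alen)
  a1 <- a0 + alen

  muts <- rep$muts
  in_region <- function(ids) {
    p <- muts$pos[match(ids, muts$id)]
    ids[p >= a0 & p < a1]
  }

  # --- polymorphism in the analyzed intergenic stretch ------------------
  if (mode == "population-MAF") {
    fr <- rep$freq_h
    fr <- fr[fr$id %in% in_region(fr$id), , drop = FALSE]
    p <- fr$count / rep$two_N_h
    maf <- pmin(p, 1 - p)
    snp <- maf > maf_threshold
    S <- sum(snp)
    mean_maf <- if (S > 0) mean(maf[snp]) else NA_real_
    n_for_d <- rep$two_N_h
    S_all <- nrow(fr)
    pi <- sum(2 * p * (1 - p)) * n_for_d / (n_for_d - 1)
  } else {
    n_hap <- length(rep$sample_h)
    tab <- table(unlist(lapply(rep$sample_h, in_region)))
    k <- as.integer(tab)
    ids <- as.integer(names(tab))
    seg <- k > 0 & k < n_hap
    k <- k[seg]
    maf <- pmin(k, n_hap - k) / n_hap
    S <- length(k)
    mean_maf <- if (S > 0) mean(maf) else NA_real_
    n_for_d <- n_hap
    S_all <- S
    pi <- sum(2 * k * (n_hap - k) / (n_hap * (n_hap - 1)))
  }
  taj <- if (S_all >= 1 && n_for_d >= 3) tajimas_d(S_all, pi, n_for_d) else
    NA_real_

  # --- divergence: one human vs one chimp individual --------------------
  d <- NA_real_
  d_N <- NA_real_
  d_S <- NA_real_
  if (length(rep$sample_c) >= 2) {
    h1 <- rep$sample_h[[1]]
    h2 <- rep$sample_h[[2]]
    c1 <- rep$sample_c[[1]]
    c2 <- rep$sample_c[[2]]
    div_ids <- sort(unique(c(h1, h2, c1, c2, rep$fixed_h$id, rep$fixed_c$id)))
    contrib <- function(ids) {
      if (length(ids) == 0) return(0)
      dh <- .dosage(ids, h1, h2, rep$fixed_h$id)
      dc <- .dosage(ids, c1, c2, rep$fixed_c$id)
      sum(half_difference(dh, dc))
    }
    pos_all <- muts$pos[match(div_ids, muts$id)]
    cls_all <- muts$class[match(div_ids, muts$id)]
    d <- contrib(div_ids[pos_all >= a0 & pos_all < a1 &
                           cls_all == "intergenic"])
    exon_len <- sum((rep$layout$end - rep$layout$start)[
      rep$layout$type == "exon"])
    d_N <- contrib(div_ids[cls_all == "nonsynonymous"]) / (exon_len * 2 / 3)
    d_S <- contrib(div_ids[cls_all == "synonymous"]) / (exon_len * 1 / 3)
  }
  s_norm <- if (!is.na(d) && d > 0 && alen > 0) (S / alen) / (d / alen) else
    NA_real_
  data.frame(rate = rep$rate, regime = rep$regime, S = S, covered = alen,
             d = d, aligned = alen, S_norm = s_norm, mean_maf = mean_maf,
             pi = pi, pi_site = pi / alen, tajimas_D = taj,
             d_N = d_N, d_S = d_S, excluded = is.na(s_norm))
}

#' Fraction of windows with a recent beneficial fixation
#'
#' Among simulated windows, the fraction carrying at least one positively
#' selected nonsynonymous mutation that fixed on the human branch within
#' the last `horizon` (unrescaled) generations. This is the quantity the
#' mixture models translate into "how much of the genome swept recently".
#'
#' @param reps list of [run_replicate()] results.
#' @param horizon look-back time in unrescaled generations (default 20000,
#'   about one effective-population-size's worth, or 500 kyr at 25
#'   years/generation).
#' @return fraction in `[0, 1]`.
#' @export
sweep_fixation_fraction <- function(reps, horizon = 20000) {
  hit <- vapply(reps, function(r) {
    fx <- r$fixed_h
    if (nrow(fx) == 0) return(FALSE)
    cls <- r$muts$class[match(fx$id, r$muts$id)]
    s <- r$muts$s[match(fx$id, r$muts$id)]
    any(cls == "nonsynonymous" & s > 0 & fx$gen_before_present <= horizon)
  }, logical(1))
  mean(hit)
}
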