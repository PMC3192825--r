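#' Tile a genome into analysis windows away from assembly trouble spots
#'
#' Chromosomes are tiled with non-overlapping fixed-size windows (trailing
#' partial windows dropped). Windows overlapping an exclusion zone -- within
#' `exclusion` bp of an annotated centromere or telomere, or of either
#' chromosome end -- are omitted, since recombination-map and alignment
#' quality degrade near those features.
#'
#' @param chrom_lengths data frame with `chrom` and `length` (bp).
#' @param feature_annotations optional BED-style data frame of centromere /
#'   telomere intervals: `chrom`, `start`, `end` (0-based half-open).
#' @param window_size window width in bp (default 100 kb).
#' @param exclusion buffer around annotated features and chromosome ends
#'   (default 10 Mb); any overlap with a buffered zone drops the window.
#' @return data frame of windows: `chrom`, `start`, `end`.
#' @examples
#' partition_genome(data.frame(chrom = "chr1", length = 25e6))
#' @export
partition_genome <- function(chrom_lengths, feature_annotations = NULL,
                             window_size = 100000, exclusion = 10e6) {
  if (any(chrom_lengths$length <= 0)) stop_param("chromosome lengths must be positive")
  if (!is.null(feature_annotations) && nrow(feature_annotations) > 0) {
    for (i in seq_len(nrow(feature_annotations))) {
      a <- feature_annotations[i, ]
      len <- chrom_lengths$length[match(a$chrom, chrom_lengths$chrom)]
      if (is.na(len) || a$start < 0 || a$end > len || a$end <= a$start) {
        stop_param("malformed annotation at line %d (%s:%s-%s)",
                   i, a$chrom, format(a$start), format(a$end))
      }
    }
  }
  out <- lapply(seq_len(nrow(chrom_lengths)), function(ci) {
    chrom <- chrom_lengths$chrom[ci]
    len <- chrom_lengths$length[ci]
    n_win <- len %/% window_size
    if (n_win == 0) return(NULL)
    start <- (seq_len(n_win) - 1) * window_size
    end <- start + window_size
    zones <- data.frame(start = c(0, len - exclusion),
                        end = c(exclusion, len))
    if (!is.null(feature_annotations)) {
      fa <- feature_annotations[feature_annotations$chrom == chrom, ,
                                drop = FALSE]
      if (nrow(fa) > 0) {
        zones <- rbind(zones, data.frame(start = fa$start - exclusion,
                                         end = fa$end + exclusion))
      }
    }
    keep <- rep(TRUE, n_win)
    for (z in seq_len(nrow(zones))) {
      keep <- keep & !(start < zones$end[z] & end > zones$start[z])
    }
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = start[keep], end = end[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  out
}

#' Filter variant records down to analyzable biallelic SNPs
#'
#' Applies the neutral-site filters: biallelic SNPs only, one allele
#' matching the reference, no triallelic sites, nothing within 2 bp of an
#' indel or structural variant, nothing inside repeat or conserved-element
#' masks, and (when a coverage mask is supplied) only sites with sequencing
#' coverage. Indels and structural variants are recognized by multi-base
#' alleles or a logical `is_sv` column; they seed the proximity filter and
#' are themselves removed.
#'
#' @param variants data frame sorted by `chrom`, `pos` with columns `chrom`,
#'   `pos` (0-based), `ref`, `alt` (comma-separated if multiallelic);
#'   optional `is_sv`, and optional `alleles` (comma-separated observed
#'   alleles when they may differ from ref/alt).
#' @param masks list with optional interval data frames `repeats`,
#'   `conserved`, `coverage` (each `chrom`, `start`, `end`).
#' @param indel_distance minimum distance (bp) from an indel/SV for a SNP
#'   to survive; sites at distance `< indel_distance` are removed, sites at
#'   exactly `indel_distance` are retained.
#' @return the surviving SNP rows of `variants`.
#' @export
ingest_variants <- function(variants, masks = NULL, indel_distance = 2) {
  if (nrow(variants) > 1) {
    o <- order(variants$chrom, variants$pos)
    if (!identical(o, seq_len(nrow(variants)))) {
      stop_param("variant records must be sorted by chromosome and position")
    }
  }
  alt_list <- strsplit(as.character(variants$alt), ",")
  is_sv <- if ("is_sv" %in% names(variants)) variants$is_sv else
    rep(FALSE, nrow(variants))
  is_indel <- is_sv | nchar(variants$ref) != 1 |
    vapply(alt_list, function(a) any(nchar(a) != 1), logical(1))
  # proximity to indels / SVs (within the same chromosome)
  near_indel <- rep(FALSE, nrow(variants))
  for (chrom in unique(variants$chrom)) {
    rows <- which(variants$chrom == chrom)
    ip <- variants$pos[rows][is_indel[rows]]
    if (length(ip) == 0) next
    for (r in rows) {
      near_indel[r] <- any(abs(variants$pos[r] - ip) < indel_distance)
    }
  }
  n_alleles <- lengths(alt_list) + 1
  ref_ok <- rep(TRUE, nrow(variants))
  if ("alleles" %in% names(variants)) {
    obs <- strsplit(as.character(variants$alleles), ",")
    n_alleles <- lengths(obs)
    ref_ok <- mapply(function(o, r) r %in% o, obs, variants$ref)
  }
  keep <- !is_indel & !near_indel & n_alleles <= 2 & ref_ok
  keep <- keep & !.in_mask(variants, masks$repeats) &
    !.in_mask(variants, masks$conserved)
  if (!is.null(masks$coverage)) {
    keep <- keep & .in_mask(variants, masks$coverage)
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read variant records from a VCF file
#'
#' Thin importer producing the data frame [ingest_variants()] expects
#' (`chrom`, `pos` 0-based, `ref`, `alt`). Requires the `vcfR` package.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return data frame sorted by `chrom`, `pos`.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_param("reading VCF files requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM,
                    pos = as.numeric(fix$POS) - 1,  # VCF is 1-based
                    ref = fix$REF, alt = fix$ALT)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.in_mask <- function(variants, set) {
  if (is.null(set) || nrow(set) == 0) return(rep(FALSE, nrow(variants)))
  hit <- rep(FALSE, nrow(variants))
  for (chrom in unique(variants$chrom)) {
    rows <- which(variants$chrom == chrom)
    s <- set[set$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0) next
    q <- IRanges::IRanges(variants$pos[rows] + 1, width = 1)
    subj <- IRanges::IRanges(s$start + 1, s$end)
    hit[rows] <- IRanges::overlapsAny(q, subj)
  }
  hit
}

# bases of `window` (list with start/end) covered by interval set `set`,
# excluding interval sets in `minus`
.window_bases <- function(window, set, minus = list()) {
  win <- IRanges::IRanges(window$start + 1, window$end)
  iv <- if (is.null(set)) win else {
    s <- set[set$chrom == window$chrom, , drop = FALSE]
    IRanges::intersect(IRanges::reduce(IRanges::IRanges(s$start + 1, s$end)),
                       win)
  }
  for (m in minus) {
    if (is.null(m)) next
    s <- m[m$chrom == window$chrom, , drop = FALSE]
    if (nrow(s) == 0) next
    iv <- IRanges::setdiff(iv,
                           IRanges::reduce(IRanges::IRanges(s$start + 1,
                                                            s$end)))
  }
  sum(IRanges::width(iv))
}

#' Summarize one genomic window
#'
#' Computes the per-window quantities used throughout the correlation
#' analyses: SNP count `S`, covered bases after masks, interspecies
#' difference count `d` and aligned bases, divergence-normalized SNP
#' density `S_norm`, mean minor allele frequency, nucleotide diversity `pi`
#' and Tajima's D (when a genotype matrix is available), GC content over
#' included bases, genic fraction and window class.
#'
#' `S_norm` defaults to the scale-free form `(S / covered) / (d / aligned)`;
#' `normalize_aligned = FALSE` restores the raw form `(S / covered) / d`.
#'
#' @param window list or one-row data frame with `chrom`, `start`, `end`.
#' @param snps pre-filtered SNPs (see [ingest_variants()]); an optional
#'   `maf` column feeds the mean-MAF summary, an optional `het_count`
#'   column feeds the heterozygosity outlier filter.
#' @param masks list of interval data frames: `coverage`, `repeats`,
#'   `conserved`, `aligned` (any may be `NULL`).
#' @param hc_diffs interspecies difference sites (`chrom`, `pos`), already
#'   filtered to unmasked aligned bases.
#' @param transcripts transcript intervals (`chrom`, `start`, `end`).
#' @param sample_size number of chromosomes behind the genotype data
#'   (needed for Tajima's D).
#' @param genotypes optional site-by-individual dosage matrix (0/1/2,
#'   complete data) for SNPs in the window, used for `pi` and Tajima's D.
#' @param gc optional GC fraction of the included bases (supplied by the
#'   caller when sequence is at hand).
#' @param normalize_aligned logical; see above.
#' @return one-row data frame with the summary fields plus `excluded`
#'   (TRUE when `S_norm` is undefined because `covered` or `d` is zero).
#' @export
summarize_window <- function(window, snps, masks, hc_diffs,
                             transcripts = NULL, sample_size = NULL,
                             genotypes = NULL, gc = NA_real_,
                             normalize_aligned = TRUE) {
  window <- as.list(window)
  in_win <- function(df) {
    if (is.null(df)) df <- data.frame(chrom = character(), pos = numeric())
    df[df$chrom == window$chrom & df$pos >= window$start &
         df$pos < window$end, , drop = FALSE]
  }
  s_in <- in_win(snps)
  d_in <- in_win(hc_diffs)
  S <- nrow(s_in)
  d <- nrow(d_in)
  covered <- .window_bases(window, masks$coverage,
                           list(masks$repeats, masks$conserved))
  aligned <- .window_bases(window, masks$aligned,
                           list(masks$repeats, masks$conserved))
  genic_bases <- if (is.null(transcripts)) 0 else
    .window_bases(window, transcripts)
  genic_frac <- genic_bases / (window$end - window$start)

  s_norm <- NA_real_
  excluded <- covered == 0 || d == 0
  if (!excluded) {
    s_norm <- if (normalize_aligned) {
      if (aligned == 0) NA_real_ else (S / covered) / (d / aligned)
    } else {
      (S / covered) / d
    }
    if (is.na(s_norm)) excluded <- TRUE
  }
  mean_maf <- if (S > 0 && "maf" %in% names(s_in)) mean(s_in$maf) else
    NA_real_
  pi <- NA_real_
  taj_d <- NA_real_
  if (!is.null(genotypes) && !is.null(sample_size) && nrow(genotypes) > 0) {
    pi <- pi_from_genotypes(genotypes, sample_size)
    if (S > 0) taj_d <- tajimas_d(S, pi, sample_size)
  }
  data.frame(chrom = window$chrom, start = window$start, end = window$end,
             S = S, covered = covered, d = d, aligned = aligned,
             S_norm = s_norm, mean_maf = mean_maf, pi = pi,
             tajimas_D = taj_d, gc = gc, genic_frac = genic_frac,
             class = classify_window(genic_frac), excluded = excluded)
}

#' Nucleotide diversity from a dosage matrix
#'
#' Mean number of pairwise differences over all chromosome pairs, summed
#' over sites: each site with minor allele count `k` out of `n` chromosomes
#' contributes `2 k (n - k) / (n (n - 1))`.
#'
#' @param genotypes site-by-individual dosage matrix (0/1/2).
#' @param n_chrom number of chromosomes (`2 *` individuals for diploids).
#' @return pairwise diversity (per window, not per base).
#' @export
pi_from_genotypes <- function(genotypes, n_chrom) {
  k <- rowSums(genotypes)
  sum(2 * k * (n_chrom - k) / (n_chrom * (n_chrom - 1)))
}

#' Tajima's D
#'
#' Normalized difference between pairwise diversity and the
#' segregating-sites estimator of the population mutation rate, with the
#' standard coefficients.
#'
#' @param S number of segregating sites (>= 1).
#' @param pi mean pairwise differences over the same sites.
#' @param n number of sampled chromosomes (>= 3).
#' @return Tajima's D, or `NA` with a warning for undefined input.
#' @examples
#' tajimas_d(S = 16, pi = 3.888889, n = 10)
#' @export
tajimas_d <- function(S, pi, n) {
  if (S < 1 || n < 3) {
    warning("Tajima's D undefined for S < 1 or n < 3")
    return(NA_real_)
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Heterozygosity outlier filter for small-panel windows
#'
#' Windows where many SNPs are heterozygous in most individuals are
#' characteristic of mismapped segmental duplications. A window is dropped
#' when it has at least `min_snps` SNPs and the mean number of heterozygous
#' genotypes per SNP (out of `n_ind`) strictly exceeds `het_mean`.
#'
#' @param window_snp_het_counts integer vector: per-SNP count of
#'   heterozygous individuals in the window.
#' @param min_snps,het_mean,n_ind filter parameters (defaults 10, 3, 6).
#' @return `TRUE` to keep the window, `FALSE` to drop it.
#' @export
cgs_het_filter <- function(window_snp_het_counts, min_snps = 10,
                           het_mean = 3, n_ind = 6) {
  if (any(window_snp_het_counts < 0 | window_snp_het_counts > n_ind)) {
    stop_param("heterozygote counts must lie in [0, %d]", n_ind)
  }
  S <- length(window_snp_het_counts)
  !(S >= min_snps && mean(window_snp_het_counts) > het_mean)
}

#' Classify a window by genic content
#'
#' @param genic_frac fraction of the window overlapping a transcript.
#' @return `"nongenic"` (no overlap), `"genic"` (at least half), or
#'   `"neither"` (in between; excluded from genic/non-genic contrasts).
#' @export
classify_window <- function(genic_frac) {
  if (any(genic_frac < 0 | genic_frac > 1)) {
    stop_param("genic_frac must lie in [0, 1]")
  }
  ifelse(genic_frac == 0, "nongenic",
         ifelse(genic_frac >= 0.5, "genic", "neither"))
}
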