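#' Generate BED-style mask sets for a window
#'
#' Emits repeat, conserved-element, sequencing-coverage, and transcript
#' interval sets for one genomic window, in 0-based half-open (BED)
#' coordinates. Repeat / conserved / coverage masks use a Bernoulli block
#' model: the window is tiled into fixed-size blocks and each block is
#' masked independently with the requested probability, so the realized
#' masked fraction is binomial around the request. Adjacent and overlapping
#' masked blocks are merged (interval normalization), never an error.
#'
#' @param window window interval: `list(chrom =, start =, end =)` (0-based
#'   half-open) or a numeric `c(start, end)` on chromosome `"chr1"`.
#' @param repeat_frac,conserved_frac,covered_frac target masked fractions in
#'   `[0, 1]` (coverage defaults to complete coverage).
#' @param gene_layout transcript layout: either a data frame with `start`,
#'   `end` columns (used as-is, clipped to the window) or a list
#'   `list(n_genes =, gene_length =)` placing that many non-anchored genes
#'   uniformly at random.
#' @param block repeat/conserved/coverage block size in bp.
#' @param seed integer seed.
#' @return A list of class `mask_set` with data frames `repeats`,
#'   `conserved`, `coverage`, `transcripts`, each with `chrom`, `start`,
#'   `end` columns, plus the `window`.
#' @examples
#' m <- gen_masks(list(chrom = "chr1", start = 0, end = 1e5),
#'                repeat_frac = 0.45, conserved_frac = 0.05, seed = 1)
#' sum(m$repeats$end - m$repeats$start) / 1e5
#' @export
gen_masks <- function(window, repeat_frac = 0.45, conserved_frac = 0.05,
                      gene_layout = list(n_genes = 1, gene_length = 30000),
                      covered_frac = 1, block = 200, seed = 1) {
  if (is.numeric(window) && length(window) == 2) {
    window <- list(chrom = "chr1", start = window[1], end = window[2])
  }
  for (f in c(repeat_frac, conserved_frac, covered_frac)) {
    if (f < 0 || f > 1) stop_param("mask fractions must lie in [0, 1]")
  }
  set.seed(seed)
  w0 <- window$start
  w1 <- window$end

  blocks_mask <- function(frac) {
    if (frac == 0) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    }
    starts <- seq(w0, w1 - 1, by = block)
    ends <- pmin(starts + block, w1)
    on <- runif(length(starts)) < frac
    .merge_intervals(data.frame(chrom = window$chrom,
                                start = starts[on], end = ends[on]))
  }

  repeats <- blocks_mask(repeat_frac)
  conserved <- blocks_mask(conserved_frac)
  coverage <- blocks_mask(covered_frac)

  if (is.data.frame(gene_layout)) {
    tx <- data.frame(chrom = window$chrom,
                     start = pmax(gene_layout$start, w0),
                     end = pmin(gene_layout$end, w1))
    tx <- .merge_intervals(tx[tx$end > tx$start, , drop = FALSE])
  } else {
    n_genes <- gene_layout$n_genes %||% 0
    glen <- gene_layout$gene_length %||% 0
    if (n_genes > 0 && glen > 0) {
      gs <- runif(n_genes, w0, max(w0, w1 - glen))
      tx <- .merge_intervals(data.frame(chrom = window$chrom,
                                        start = floor(gs),
                                        end = pmin(floor(gs) + glen, w1)))
    } else {
      tx <- data.frame(chrom = character(), start = numeric(), end = numeric())
    }
  }

  structure(list(repeats = repeats, conserved = conserved,
                 coverage = coverage, transcripts = tx, window = window),
            class = "mask_set")
}

# Union of possibly overlapping intervals on one chromosome (0-based,
# half-open); adjacent intervals are merged.
.merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1, end = df$end))
  data.frame(chrom = df$chrom[1], start = IRanges::start(ir) - 1,
             end = IRanges::end(ir))
}

#' Total number of bases covered by an interval set
#' @param bed data frame with `start` and `end` (0-based half-open).
#' @return total covered bases after interval normalization.
#' @export
mask_bases <- function(bed) {
  if (nrow(bed) == 0) return(0)
  m <- .merge_intervals(bed)
  sum(m$end - m$start)
}

#' Write a BED-style mask to disk
#' @param bed data frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(bed, path) {
  write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file
#' @param path BED path.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE)
  setNames(x[, 1:3], c("chrom", "start", "end"))
}
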