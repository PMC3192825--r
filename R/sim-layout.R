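#' Build the exon / intron / intergenic layout of a simulated window
#'
#' The default window is 100 kb: a gene of 8 exons (1.5 kb each) and 7
#' introns (5 kb each) totalling 47 kb, split at its midpoint -- which
#' falls in the middle of the central intron -- around a 53 kb neutral
#' intergenic block. Exonic bases carry codon-position annotation
#' (cumulative exonic offset mod 3; positions 1-2 are nonsynonymous
#' targets, position 3 synonymous), with the reading frame running across
#' exons in genomic order.
#'
#' @param config list with `n_exons`, `n_introns`, `exon_length`,
#'   `intron_length`, `intergenic_length` (bp). Defaults: 8, 7, 1500, 5000,
#'   53000. `n_introns` must be `n_exons - 1` and the gene midpoint must
#'   fall inside an intron so no codon is split.
#' @return data frame of class `window_layout` with `start`, `end` (0-based
#'   half-open), `type` (`exon` / `intron` / `intergenic`), `exon_cum`
#'   (cumulative exonic bp before each feature), and attribute
#'   `window_length`.
#' @examples
#' lay <- build_layout()
#' sum(lay$end - lay$start)                     # 100000
#' lay$end[lay$type == "intergenic"] - lay$start[lay$type == "intergenic"]
#' @export
build_layout <- function(config = list()) {
  n_ex <- config$n_exons %||% 8
  n_in <- config$n_introns %||% 7
  ex_len <- config$exon_length %||% 1500
  in_len <- config$intron_length %||% 5000
  ig_len <- config$intergenic_length %||% 53000
  if (n_in != n_ex - 1) stop_param("need n_introns = n_exons - 1")
  if (min(ex_len, in_len, ig_len) <= 0) stop_param("lengths must be positive")
  if (ex_len %% 3 != 0) stop_param("exon length must be a multiple of 3")

  # gene = E I E I ... E; split at its midpoint around the intergenic block
  types <- rep(c("exon", "intron"), length.out = 2 * n_ex - 1)
  lens <- ifelse(types == "exon", ex_len, in_len)
  gene_len <- sum(lens)
  mid <- gene_len / 2
  ends <- cumsum(lens)
  starts <- ends - lens
  split_i <- which(starts < mid & ends > mid)
  if (types[split_i] != "intron") {
    stop_param("gene midpoint falls in an exon; adjust lengths")
  }
  left <- data.frame(type = c(types[seq_len(split_i - 1)], "intron"),
                     len = c(lens[seq_len(split_i - 1)], mid - starts[split_i]))
  right <- data.frame(type = c("intron", types[seq(split_i + 1, 2 * n_ex - 1)]),
                      len = c(ends[split_i] - mid,
                              lens[seq(split_i + 1, 2 * n_ex - 1)]))
  feats <- rbind(left,
                 data.frame(type = "intergenic", len = ig_len),
                 right)
  feats$end <- cumsum(feats$len)
  feats$start <- feats$end - feats$len
  # cumulative exonic offset (reading frame across exons)
  feats$exon_cum <- cumsum(c(0, head(ifelse(feats$type == "exon",
                                            feats$len, 0), -1)))
  out <- feats[, c("start", "end", "type", "exon_cum")]
  rownames(out) <- NULL
  total <- sum(out$end - out$start)
  expected <- n_ex * ex_len + n_in * in_len + ig_len
  if (abs(total - expected) > 1e-9) stop_param("layout lengths inconsistent")
  attr(out, "window_length") <- total
  class(out) <- c("window_layout", "data.frame")
  out
}

#' @export
print.window_layout <- function(x, ...) {
  cat(sprintf("window layout: %d bp, %d exons / %d introns, %d bp intergenic\n",
              attr(x, "window_length"), sum(x$type == "exon"),
              sum(x$type == "intron") - 1,
              sum((x$end - x$start)[x$type == "intergenic"])))
  invisible(x)
}

# intergenic block coordinates (largest intergenic feature)
.intergenic_block <- function(layout) {
  ig <- layout[layout$type == "intergenic", , drop = FALSE]
  ig[which.max(ig$end - ig$start), c("start", "end")]
}
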