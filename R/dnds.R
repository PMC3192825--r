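#' @title Nei-Gojobori synonymous / nonsynonymous accounting
#' @name dnds
#' @description Site counting and per-difference classification for coding
#'   sequence divergence between two species, following the Nei-Gojobori
#'   convention: each codon position contributes a synonymous-site fraction
#'   equal to the proportion of its three possible single-base changes that
#'   preserve the amino acid, and each observed single-base difference is
#'   classified by substituting the second species' base into the first
#'   species' codon.
NULL

.BASES <- c("A", "C", "G", "T")

# 64 codons and their amino acids under the standard code.
.codon_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- as.character(gc_tab)
  names(aa) <- codons
  # synonymous fraction of each codon position: share of the 3 possible
  # single-base changes that leave the amino acid unchanged
  syn <- matrix(NA_real_, 64, 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    if (aa[cd] == "*") next
    sp <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      alts <- .BASES[.BASES != sp[p]]
      n_syn <- 0
      for (b in alts) {
        alt <- sp
        alt[p] <- b
        if (aa[paste(alt, collapse = "")] == aa[cd]) n_syn <- n_syn + 1
      }
      syn[cd, p] <- n_syn / 3
    }
  }
  .codon_env$aa <- aa
  .codon_env$syn <- syn
  .codon_env
}

#' Count synonymous and nonsynonymous sites in a coding sequence
#'
#' Sites are counted from the first species' sequence only (no averaging
#' with the second species). Codons containing an internal stop are skipped
#' with a warning; bases flagged ineligible contribute zero to both counts.
#'
#' @param cds coding sequence (character scalar or `DNAString`), length a
#'   multiple of 3, read in frame.
#' @param eligibility_mask logical vector, one flag per base of `cds`
#'   (default: all eligible). Masked-out bases contribute to neither count.
#' @return named numeric vector `c(L_N =, L_S =)`; `L_N + L_S` equals three
#'   times the number of fully eligible non-stop codons.
#' @examples
#' count_sites("TTTGGG")  # Phe + Gly: L_S = 1/3 + 1
#' @export
count_sites <- function(cds, eligibility_mask = NULL) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3 != 0) stop_param("CDS length (%d) is not a multiple of 3", n)
  if (is.null(eligibility_mask)) eligibility_mask <- rep(TRUE, n)
  if (length(eligibility_mask) != n) {
    stop_param("eligibility mask length does not match the CDS")
  }
  tab <- .codon_table()
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  L_N <- 0
  L_S <- 0
  skipped <- 0
  for (i in seq_along(codons)) {
    cd <- codons[i]
    if (grepl("[^ACGT]", cd)) next
    if (tab$aa[cd] == "*") {
      skipped <- skipped + 1
      next
    }
    for (p in 1:3) {
      if (!eligibility_mask[(i - 1) * 3 + p]) next
      fs <- tab$syn[cd, p]
      L_S <- L_S + fs
      L_N <- L_N + (1 - fs)
    }
  }
  if (skipped > 0) {
    warning(sprintf("%d internal stop codon(s) skipped", skipped))
  }
  c(L_N = unname(L_N), L_S = unname(L_S))
}

#' Classify a single-site coding difference
#'
#' The other two codon positions are held at the first species' bases; the
#' substituted codon is translated and compared. Changes to or from a stop
#' codon are nonsynonymous; ambiguous bases make the site unclassifiable.
#'
#' @param codon_human the first species' codon (3 characters).
#' @param position_in_codon 0, 1 or 2 (0-based position within the codon).
#' @param chimp_base the second species' base at that position.
#' @return `"synonymous"`, `"nonsynonymous"`, `"none"` (identical base), or
#'   `NA` if either codon contains an ambiguous base.
#' @examples
#' classify_difference("TTT", 2, "C")  # Phe -> Phe
#' classify_difference("TTT", 2, "A")  # Phe -> Leu
#' @export
classify_difference <- function(codon_human, position_in_codon, chimp_base) {
  codon_human <- toupper(codon_human)
  chimp_base <- toupper(chimp_base)
  if (grepl("[^ACGT]", codon_human) || !(chimp_base %in% .BASES)) {
    return(NA_character_)
  }
  stopifnot(position_in_codon %in% 0:2)
  sp <- strsplit(codon_human, "")[[1]]
  if (sp[position_in_codon + 1] == chimp_base) return("none")
  tab <- .codon_table()
  alt <- sp
  alt[position_in_codon + 1] <- chimp_base
  aa1 <- tab$aa[codon_human]
  aa2 <- tab$aa[paste(alt, collapse = "")]
  if (aa1 == aa2) "synonymous" else "nonsynonymous"
}

#' Per-window synonymous / nonsynonymous divergence
#'
#' Assigns interspecies alignment differences to coding positions of each
#' window's gene models, classifies them, and returns Nei-Gojobori counts.
#' When several gene models overlap, only the longest is kept. Repeat-masked
#' positions are excluded from both site and difference counts; conserved
#' elements are deliberately not masked here (coding sites are under direct
#' selection, and divergence at them is the quantity of interest).
#'
#' @param windows data frame of windows with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [partition_genome()].
#' @param annotations data frame of single-interval gene models with
#'   `gene_id`, `chrom`, `start`, `end`, `strand` and an attribute `seqs`, a
#'   named character vector of spliced CDS (5'->3') per `gene_id`.
#' @param hc_diffs data frame of alignment differences: `chrom`, `pos`
#'   (0-based), `human_base`, `chimp_base`.
#' @param masks optional list with `repeats` and `aligned` interval data
#'   frames; `NULL` elements mean no repeat mask / everything aligned.
#' @return data frame, one row per window: `D_N`, `D_S`, `L_N`, `L_S`,
#'   `d_N = D_N / L_N`, `d_S = D_S / L_S` (NA when the denominator is 0).
#' @export
window_dnds <- function(windows, annotations, hc_diffs, masks = NULL) {
  seqs <- attr(annotations, "seqs")
  out <- data.frame(windows[, c("chrom", "start", "end")],
                    D_N = 0, D_S = 0, L_N = 0, L_S = 0)
  excl <- masks$repeats
  alig <- masks$aligned
  in_set <- function(pos, chrom, set) {
    if (is.null(set) || nrow(set) == 0) return(rep(FALSE, length(pos)))
    hit <- rep(FALSE, length(pos))
    s <- set[set$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      hit <- hit | (pos >= s$start[i] & pos < s$end[i])
    }
    hit
  }
  for (w in seq_len(nrow(out))) {
    g <- annotations[annotations$chrom == out$chrom[w] &
                       annotations$start < out$end[w] &
                       annotations$end > out$start[w], , drop = FALSE]
    if (nrow(g) == 0) next
    # resolve overlapping models: keep the longest in each overlap cluster
    g <- g[order(g$end - g$start, decreasing = TRUE), , drop = FALSE]
    kept <- g[0, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      if (nrow(kept) == 0 ||
          all(g$start[i] >= kept$end | g$end[i] <= kept$start)) {
        kept <- rbind(kept, g[i, , drop = FALSE])
      }
    }
    for (i in seq_len(nrow(kept))) {
      gid <- kept$gene_id[i]
      cds <- toupper(seqs[[gid]])
      glen <- nchar(cds)
      gpos <- kept$start[i]:(kept$end[i] - 1)   # genomic positions of CDS
      if (length(gpos) != glen) {
        stop_param("gene %s: CDS length does not match its interval", gid)
      }
      # CDS coordinate of each genomic position (minus strand read backwards)
      cpos <- if (kept$strand[i] == "-") rev(seq_len(glen)) else seq_len(glen)
      eligible <- gpos >= out$start[w] & gpos < out$end[w] &
        !in_set(gpos, out$chrom[w], excl) &
        (if (is.null(alig)) TRUE else in_set(gpos, out$chrom[w], alig))
      mask_cds <- logical(glen)
      mask_cds[cpos[eligible]] <- TRUE
      L <- count_sites(cds, mask_cds)
      out$L_N[w] <- out$L_N[w] + L[["L_N"]]
      out$L_S[w] <- out$L_S[w] + L[["L_S"]]
      d <- hc_diffs[hc_diffs$chrom == out$chrom[w] &
                      hc_diffs$pos %in% gpos[eligible], , drop = FALSE]
      for (j in seq_len(nrow(d))) {
        cp <- cpos[match(d$pos[j], gpos)]
        codon_i <- (cp - 1) %/% 3
        codon <- substr(cds, codon_i * 3 + 1, codon_i * 3 + 3)
        pic <- (cp - 1) %% 3
        cb <- d$chimp_base[j]
        if (kept$strand[i] == "-") cb <- .revcomp_base(cb)
        cls <- classify_difference(codon, pic, cb)
        if (is.na(cls)) next
        if (cls == "nonsynonymous") out$D_N[w] <- out$D_N[w] + 1
        if (cls == "synonymous") out$D_S[w] <- out$D_S[w] + 1
      }
    }
  }
  out$d_N <- ifelse(out$L_N > 0, out$D_N / out$L_N, NA_real_)
  out$d_S <- ifelse(out$L_S > 0, out$D_S / out$L_S, NA_real_)
  out
}

.revcomp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]
}
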