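#' Generate a toy human/chimp CDS alignment with planted differences
#'
#' Builds a random stop-free coding sequence and plants exactly the
#' requested numbers of synonymous and nonsynonymous single-base
#' differences, each in a distinct codon, so the Nei-Gojobori classifier
#' can be validated by round-trip.
#'
#' @param n_codons number of codons.
#' @param n_syn_diffs,n_nonsyn_diffs numbers of synonymous / nonsynonymous
#'   single-site differences to plant (must fit: one difference per codon).
#' @param seed integer seed.
#' @return list of class `cds_alignment`: `human`, `chimp` (character
#'   sequences of `3 * n_codons` bases) and `diffs`, a data frame with
#'   `codon` (1-based), `pos_in_codon` (0-based), `human_base`,
#'   `chimp_base`, `type`.
#' @examples
#' aln <- gen_cds_alignment(50, n_syn_diffs = 3, n_nonsyn_diffs = 5, seed = 1)
#' table(aln$diffs$type)
#' @export
gen_cds_alignment <- function(n_codons, n_syn_diffs = 0, n_nonsyn_diffs = 0,
                              seed = 1) {
  if (n_syn_diffs < 0 || n_nonsyn_diffs < 0) {
    stop_param("difference counts must be non-negative")
  }
  if (n_syn_diffs + n_nonsyn_diffs > n_codons) {
    stop_param(paste0("cannot place %d differences in %d codons ",
                      "(one difference per codon)"),
               n_syn_diffs + n_nonsyn_diffs, n_codons)
  }
  set.seed(seed)
  tab <- .codon_table()
  sense <- names(tab$aa)[tab$aa != "*"]
  # codons admitting a synonymous single-base change
  syn_capable <- sense[rowSums(tab$syn[sense, , drop = FALSE]) > 0]
  # every sense codon admits a nonsynonymous non-stop change
  nonsyn_choices <- function(cd) {
    sp <- strsplit(cd, "")[[1]]
    out <- NULL
    for (p in 1:3) {
      for (b in .BASES[.BASES != sp[p]]) {
        alt <- sp
        alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (tab$aa[altc] != "*" && tab$aa[altc] != tab$aa[cd]) {
          out <- rbind(out, data.frame(pos = p - 1, base = b))
        }
      }
    }
    out
  }
  syn_choices <- function(cd) {
    sp <- strsplit(cd, "")[[1]]
    out <- NULL
    for (p in 1:3) {
      for (b in .BASES[.BASES != sp[p]]) {
        alt <- sp
        alt[p] <- b
        if (tab$aa[paste(alt, collapse = "")] == tab$aa[cd]) {
          out <- rbind(out, data.frame(pos = p - 1, base = b))
        }
      }
    }
    out
  }

  human <- sample(sense, n_codons, replace = TRUE)
  idx <- sample.int(n_codons, n_syn_diffs + n_nonsyn_diffs)
  syn_idx <- head(idx, n_syn_diffs)
  non_idx <- idx[seq_len(n_nonsyn_diffs) + n_syn_diffs]
  # make sure codons chosen for synonymous changes can host one
  for (i in syn_idx) {
    if (!(human[i] %in% syn_capable)) human[i] <- sample(syn_capable, 1)
  }
  chimp <- human
  diffs <- NULL
  plant <- function(i, choices, type) {
    ch <- choices(human[i])
    pick <- ch[sample.int(nrow(ch), 1), ]
    sp <- strsplit(chimp[i], "")[[1]]
    hb <- sp[pick$pos + 1]
    sp[pick$pos + 1] <- pick$base
    chimp[i] <<- paste(sp, collapse = "")
    diffs <<- rbind(diffs, data.frame(
      codon = i, pos_in_codon = pick$pos, human_base = hb,
      chimp_base = pick$base, type = type))
  }
  for (i in syn_idx) plant(i, syn_choices, "synonymous")
  for (i in non_idx) plant(i, nonsyn_choices, "nonsynonymous")
  if (is.null(diffs)) {
    diffs <- data.frame(codon = integer(), pos_in_codon = integer(),
                        human_base = character(), chimp_base = character(),
                        type = character())
  }
  diffs <- diffs[order(diffs$codon), , drop = FALSE]
  rownames(diffs) <- NULL
  structure(list(human = paste(human, collapse = ""),
                 chimp = paste(chimp, collapse = ""),
                 diffs = diffs),
            class = "cds_alignment")
}

#' Write a CDS alignment pair to FASTA
#' @param aln a `cds_alignment`.
#' @param path output FASTA path.
#' @export
write_cds_fasta <- function(aln, path) {
  x <- Biostrings::DNAStringSet(c(human = aln$human, chimp = aln$chimp))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a two-sequence CDS FASTA back into a `cds_alignment`
#' @param path FASTA path with sequences named `human` and `chimp`.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(list(human = as.character(x[["human"]]),
                 chimp = as.character(x[["chimp"]]),
                 diffs = NULL),
            class = "cds_alignment")
}
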