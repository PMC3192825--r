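#' Simulate low-coverage pileup read counts with known allele frequencies
#'
#' Generates per-site, per-individual base counts that mimic a pooled
#' low-coverage resequencing experiment: each diploid individual's genotype
#' is drawn under Hardy-Weinberg equilibrium at the site's true minor allele
#' frequency, a sequencing depth is drawn for every individual from
#' `depth_law`, each read is copied from one of the individual's two
#' chromosomes, and with probability `e` a read is miscalled, uniformly, as
#' one of the other three bases.
#'
#' @param q_true numeric vector of true population minor allele frequencies,
#'   one per site, each in `[0, 0.5]`.
#' @param depth_law per-individual sequencing depth distribution, a list such
#'   as `list(dist = "poisson", mean = 0.2)`, `list(dist = "fixed", depth = 2)`
#'   or `list(dist = "nbinom", mean = 0.2, size = 1)`.
#' @param e per-read miscall probability (scalar, `0 <= e < 0.75`).
#' @param n_ind number of diploid individuals.
#' @param ploidy ploidy; only `2` is supported.
#' @param seed integer seed.
#'
#' @return An object of class `pileup_panel`: a list with `sites` (data frame
#'   with `site`, `major`, `minor`, `q_true`), `counts` (long data frame with
#'   `site`, `ind`, `A`, `C`, `G`, `T`, one row per individual with at least
#'   one read), and scalars `e`, `n_ind`.
#' @examples
#' p <- gen_pileups(c(0, 0.2), list(dist = "poisson", mean = 2),
#'                  e = 0.01, n_ind = 50, seed = 1)
#' head(p$counts)
#' @export
gen_pileups <- function(q_true, depth_law = list(dist = "poisson", mean = 0.2),
                        e = 0.01, n_ind = 2000, ploidy = 2, seed = 1) {
  if (any(q_true < 0 | q_true > 0.5)) {
    stop_param("q_true must lie in [0, 0.5]")
  }
  if (length(e) != 1 || e < 0 || e >= 0.75) {
    stop_param("e must be a scalar in [0, 0.75)")
  }
  if (ploidy != 2) stop_param("only diploid individuals are supported")
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  n_sites <- length(q_true)
  alle <- t(vapply(seq_len(n_sites), function(i) sample(bases, 2), character(2)))

  per_site <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    depth <- .draw_depths(depth_law, n_ind)
    keep <- which(depth > 0)
    if (length(keep) == 0) next
    d <- depth[keep]
    g <- rbinom(length(keep), 2, q_true[s])       # minor allele dosage, HWE
    m_true <- rbinom(length(keep), d, g / 2)      # reads from the minor allele
    M_true <- d - m_true
    # uniform miscall to each of the other three bases
    cnt <- matrix(0L, length(keep), 4, dimnames = list(NULL, bases))
    maj <- alle[s, 1]; mnr <- alle[s, 2]
    err_M <- rbinom(length(keep), M_true, e)
    err_m <- rbinom(length(keep), m_true, e)
    cnt[, maj] <- M_true - err_M
    cnt[, mnr] <- m_true - err_m
    others_M <- setdiff(bases, maj)
    others_m <- setdiff(bases, mnr)
    for (i in which(err_M > 0)) {
      spill <- rmultinom(1, err_M[i], rep(1 / 3, 3))[, 1]
      cnt[i, others_M] <- cnt[i, others_M] + spill
    }
    for (i in which(err_m > 0)) {
      spill <- rmultinom(1, err_m[i], rep(1 / 3, 3))[, 1]
      cnt[i, others_m] <- cnt[i, others_m] + spill
    }
    per_site[[s]] <- data.frame(site = s, ind = keep, cnt,
                                check.names = FALSE)
  }
  counts <- do.call(rbind, per_site)
  if (is.null(counts)) {
    counts <- data.frame(site = integer(), ind = integer(),
                         A = integer(), C = integer(),
                         G = integer(), T = integer())
  }
  structure(list(
    sites = data.frame(site = seq_len(n_sites), major = alle[, 1],
                       minor = alle[, 2], q_true = q_true),
    counts = counts, e = e, n_ind = n_ind
  ), class = "pileup_panel")
}

#' @importFrom stats rmultinom
.draw_depths <- function(law, n) {
  switch(law$dist,
    poisson = rpois(n, law$mean),
    fixed   = rep(as.integer(law$depth), n),
    nbinom  = rnbinom(n, size = law$size, mu = law$mean),
    stop_param("unknown depth law '%s'", law$dist)
  )
}

#' Write / read a pileup panel as TSV
#'
#' Long format with one row per site x individual:
#' `site  ind  A  C  G  T  e`.
#' @param panel a `pileup_panel`.
#' @param path file path.
#' @return `read_pileup_tsv` returns a `pileup_panel` (without ground truth,
#'   which a real experiment would not know; `sites$q_true` is `NA`).
#' @export
write_pileup_tsv <- function(panel, path) {
  out <- panel$counts
  out$e <- panel$e
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  x <- read.delim(path, check.names = FALSE)
  sites <- sort(unique(x$site))
  tot <- rowsum(as.matrix(x[, c("A", "C", "G", "T")]), x$site)
  ord <- t(apply(tot, 1, order, decreasing = TRUE))
  bases <- c("A", "C", "G", "T")
  structure(list(
    sites = data.frame(site = sites, major = bases[ord[, 1]],
                       minor = bases[ord[, 2]], q_true = NA_real_),
    counts = x[, c("site", "ind", "A", "C", "G", "T")],
    e = x$e[1], n_ind = max(x$ind)
  ), class = "pileup_panel")
}
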