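#' Downsample a site's reads to a fixed depth cap
#'
#' Low-coverage pooled designs have wildly uneven depth, which would make
#' allele-frequency estimates differentially precise across the genome.
#' Sampling a fixed number of reads per site (uniformly, without
#' replacement, across all individuals' reads) equalizes the information
#' per site. Individual-of-origin labels are preserved.
#'
#' @param counts per-individual base counts for one site: data frame or
#'   matrix with columns `A`, `C`, `G`, `T` (one row per individual; a
#'   row-name / `ind` column identifies the individual).
#' @param cap number of reads to retain (default 100).
#' @param seed optional integer seed (`NULL` leaves the RNG stream alone).
#' @return a matrix of the same shape with exactly `cap` reads in total, or
#'   `NULL` (site-skipped signal) if fewer than `cap` reads are present.
#' @export
downsample_site <- function(counts, cap = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(counts[, c("A", "C", "G", "T"), drop = FALSE])
  storage.mode(m) <- "integer"
  tot <- sum(m)
  if (tot < cap) return(NULL)
  if (tot == cap) return(m)
  cell <- as.vector(m)                    # reads laid out cell by cell
  take <- sample.int(tot, cap)            # uniform without replacement
  cum <- cumsum(cell)
  cell_of <- findInterval(take - 1L, cum) + 1L
  kept <- tabulate(cell_of, nbins = length(cell))
  out <- matrix(kept, nrow(m), 4, dimnames = dimnames(m))
  rownames(out) <- rownames(m)
  out
}

#' Method-of-moments minor allele frequency from pooled read counts
#'
#' With a uniform miscall model (a read is wrong with probability `e` and
#' then equally likely to be any other base), the expected minor-base read
#' fraction is `f = q (1 - e) + (1 - q) e / 3`, whose inversion gives the
#' estimator `q = (f - e/3) / (1 - 4 e / 3)`, clamped to `[0, 0.5]`.
#'
#' @param base_counts length-4 vector of pooled read counts (A, C, G, T).
#' @param e per-read miscall probability, `< 0.75`.
#' @param minor_base base to treat as the minor allele (requires a named
#'   count vector); default: the second-most common base. When given, the
#'   estimate is not folded (useful for evaluating against a known truth).
#' @return point estimate of the minor allele frequency in `[0, 0.5]`
#'   (or `[0, 1]` when `minor_base` is forced).
#' @examples
#' mom_maf(c(70, 30, 0, 0), e = 0)      # 0.30
#' mom_maf(c(70, 30, 0, 0), e = 0.01)   # ~0.30068
#' @export
mom_maf <- function(base_counts, e = 0, minor_base = NULL) {
  if (e >= 0.75 || e < 0) stop_param("e must lie in [0, 0.75)")
  tot <- sum(base_counts)
  if (tot <= 0) stop_param("no reads at site")
  if (is.null(minor_base)) {
    f <- sort(base_counts, decreasing = TRUE)[2] / tot
    cap <- 0.5
  } else {
    f <- base_counts[[minor_base]] / tot
    cap <- 1
  }
  q <- (f - e / 3) / (1 - 4 * e / 3)
  min(max(q, 0), cap)
}

# P(read shows the minor base | minor-allele dosage g) under uniform miscall
.p_read_minor <- function(e) {
  c(e / 3,                      # hom major
    0.5 * (1 - e) + 0.5 * e / 3,  # het
    1 - e)                      # hom minor
}

#' Maximum-likelihood minor allele frequency from a low-coverage panel
#'
#' Maximizes the population-frequency likelihood
#' \deqn{L(q) = \prod_i \sum_{g \in \{0,1,2\}} \mathrm{Binom}(k_i \mid n_i,
#'   p_g) \, \mathrm{HWE}(g \mid q)}
#' where \eqn{k_i} is individual *i*'s count of minor-base reads out of
#' \eqn{n_i} total, genotypes follow Hardy-Weinberg proportions, and
#' \eqn{p_0 = e/3}, \eqn{p_1 = (1-e)/2 + e/6}, \eqn{p_2 = 1-e} under the
#' uniform miscall model. The maximization runs over `q` in `[0, 1]` and
#' the result is folded to a minor allele frequency.
#'
#' @param panel per-individual counts for one site: matrix/data frame with
#'   columns `A`, `C`, `G`, `T`, or a two-column matrix `cbind(k, n)` of
#'   minor-base and total reads per individual.
#' @param e per-read miscall probability.
#' @param minor_base minor base letter; if `NULL` and `panel` has base
#'   columns, the second-most common base pooled over individuals is used
#'   (ties broken in A < C < G < T order).
#' @param tol optimizer tolerance on `q`.
#' @param fold fold the estimate to `[0, 0.5]` (default). `fold = FALSE`
#'   returns the raw frequency of the designated minor base in `[0, 1]`,
#'   which is the right scale when evaluating the estimator against a
#'   known simulated truth.
#' @return ML estimate of the minor allele frequency, or `NA` for an
#'   empty panel.
#' @export
ml_maf <- function(panel, e = 0, minor_base = NULL, tol = 1e-6,
                   fold = TRUE) {
  if (e >= 0.75 || e < 0) stop_param("e must lie in [0, 0.75)")
  kn <- .panel_to_kn(panel, minor_base)
  kn <- kn[kn[, 2] > 0, , drop = FALSE]
  if (nrow(kn) == 0) {
    warning("empty panel: ML estimate undefined")
    return(NA_real_)
  }
  p_g <- .p_read_minor(e)
  # per-individual binomial term for each genotype, computed once
  lik_g <- vapply(1:3, function(j) dbinom(kn[, 1], kn[, 2], p_g[j]),
                  numeric(nrow(kn)))
  negll <- function(q) {
    w <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    -sum(log(pmax(lik_g %*% w, 1e-300)))
  }
  opt <- optimize(negll, c(0, 1), tol = tol)
  q <- opt$minimum
  # the boundary is never returned exactly by golden-section; snap if flat
  if (negll(0) <= opt$objective) q <- 0
  if (negll(1) <= opt$objective) q <- 1
  if (fold) min(q, 1 - q) else q
}

.panel_to_kn <- function(panel, minor_base) {
  if (is.data.frame(panel)) panel <- as.matrix(panel[, colnames(panel) %in%
                                                       c("A", "C", "G", "T")])
  if (!is.null(colnames(panel)) && all(c("A", "C", "G", "T") %in%
                                         colnames(panel))) {
    m <- panel[, c("A", "C", "G", "T"), drop = FALSE]
    if (is.null(minor_base)) {
      pooled <- colSums(m)
      minor_base <- names(sort(pooled, decreasing = TRUE))[2]
    }
    cbind(k = m[, minor_base], n = rowSums(m))
  } else {
    if (ncol(panel) != 2) stop_param("panel must have ACGT or (k, n) columns")
    cbind(k = panel[, 1], n = panel[, 2])
  }
}

#' Two-stage SNP calling from a pileup panel
#'
#' For every site with at least `cap` reads: downsample to `cap` reads, take
#' the second-most common base as the minor allele, compute the
#' method-of-moments MAF, and refine by maximum likelihood only where the
#' MoM estimate clears the prefilter. A site is called a SNP when its ML
#' estimate strictly exceeds `threshold`. Sites with fewer than `cap` reads
#' are reported as skipped, not errors.
#'
#' @param panel a `pileup_panel` (see [gen_pileups()]).
#' @param e per-read miscall probability (defaults to the panel's).
#' @param cap read-depth cap per site.
#' @param prefilter MoM gate below which no ML estimate is attempted.
#' @param threshold ML MAF above which (strictly) a site is a SNP.
#' @param seed integer seed for the downsampling.
#' @return data frame with one row per site: `site`, `minor_base`,
#'   `depth_used`, `mom_estimate`, `ml_estimate` (NA where not attempted),
#'   `is_snp`, `tie` (minor-base tie flag), `skipped`.
#' @export
call_snps <- function(panel, e = panel$e, cap = 100, prefilter = 0.01,
                      threshold = 0.05, seed = 1) {
  set.seed(seed)
  sites <- panel$sites$site
  res <- data.frame(site = sites, minor_base = NA_character_,
                    depth_used = 0L, mom_estimate = NA_real_,
                    ml_estimate = NA_real_, is_snp = FALSE,
                    tie = FALSE, skipped = FALSE)
  for (i in seq_along(sites)) {
    rows <- panel$counts[panel$counts$site == sites[i], , drop = FALSE]
    m <- as.matrix(rows[, c("A", "C", "G", "T"), drop = FALSE])
    used <- downsample_site(m, cap = cap)
    if (is.null(used)) {
      res$skipped[i] <- TRUE
      next
    }
    pooled <- colSums(used)
    ord <- order(pooled, decreasing = TRUE)   # ties fall back to A<C<G<T
    res$minor_base[i] <- names(pooled)[ord[2]]
    res$tie[i] <- sum(pooled == pooled[ord[2]]) > 1
    res$depth_used[i] <- sum(pooled)
    res$mom_estimate[i] <- mom_maf(pooled, e)
    if (res$mom_estimate[i] > prefilter) {
      res$ml_estimate[i] <- ml_maf(used, e, minor_base = res$minor_base[i])
      res$is_snp[i] <- !is.na(res$ml_estimate[i]) &&
        res$ml_estimate[i] > threshold
    }
  }
  res
}
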