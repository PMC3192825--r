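# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation goes through Biostrings, Tajima's D
# is re-derived from a different arrangement of the coefficients, and the
# ML allele-frequency oracle is an exhaustive grid search.

# translate a codon with Biostrings (independent of the package's table)
oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# brute-force synonymous site fraction of codon position p (1..3)
oracle_syn_fraction <- function(codon, p) {
  sp <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate(codon)
  alts <- setdiff(c("A", "C", "G", "T"), sp[p])
  mean(vapply(alts, function(b) {
    alt <- sp
    alt[p] <- b
    oracle_translate(paste(alt, collapse = "")) == aa0
  }, logical(1)))
}

# brute-force classification of a single-base change
oracle_classify <- function(codon, p0, base) {
  sp <- strsplit(codon, "")[[1]]
  if (sp[p0 + 1] == base) return("none")
  alt <- sp
  alt[p0 + 1] <- base
  if (oracle_translate(codon) == oracle_translate(paste(alt, collapse = "")))
    "synonymous" else "nonsynonymous"
}

# Tajima's D from a second, independently written expression
oracle_tajima <- function(S, pi, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# exhaustive-grid ML minor allele frequency (resolution 1e-5)
oracle_ml_grid <- function(k, n, e, step = 1e-5) {
  qs <- seq(0, 1, by = step)
  p_g <- c(e / 3, 0.5 * (1 - e) + 0.5 * e / 3, 1 - e)
  ll <- vapply(qs, function(q) {
    w <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    sum(log(pmax(
      sapply(seq_along(k), function(i) {
        sum(w * dbinom(k[i], n[i], p_g))
      }), 1e-300)))
  }, numeric(1))
  q_hat <- qs[which.max(ll)]
  min(q_hat, 1 - q_hat)
}

# Spearman rho by hand: average ranks + explicit Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random stop-free CDS
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
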