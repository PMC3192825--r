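#' Generate a synthetic window feature table with a Gaussian copula
#'
#' Draws per-window genomic features (recombination rate, GC fraction, genic
#' fraction, divergence, SNP counts, ...) whose rank-correlation structure is
#' controlled by a Gaussian copula while each column keeps an arbitrary
#' marginal distribution. Under a Gaussian copula with latent correlation
#' `r`, the population Spearman correlation of any two continuous columns is
#' `(6 / pi) * asin(r / 2)`, which makes the generator easy to validate.
#'
#' @param n_windows number of windows (rows).
#' @param copula latent correlation matrix (positive semi-definite, unit
#'   diagonal), one dimension per feature.
#' @param marginals named list of marginal specs, e.g.
#'   `list(rec_rate = list(dist = "gamma", shape = 1.2, rate = 1))`.
#'   Supported `dist`: `gamma`, `exp`, `beta`, `lnorm`, `norm`, `unif`,
#'   `pois`, `nbinom`, `binom`.
#' @param seed integer seed.
#' @return A data frame (class `synthetic_window_table`) with one column per
#'   marginal; the copula, marginals and seed are kept as attributes.
#' @examples
#' cop <- diag(2); cop[1, 2] <- cop[2, 1] <- 0.9
#' tab <- gen_window_table(1000, cop,
#'   list(a = list(dist = "exp", rate = 1),
#'        b = list(dist = "beta", shape1 = 2, shape2 = 5)), seed = 1)
#' cor(tab$a, tab$b, method = "spearman")
#' @export
gen_window_table <- function(n_windows,
                             copula = default_window_copula(),
                             marginals = default_window_marginals(),
                             seed = 1) {
  k <- length(marginals)
  if (!is.matrix(copula) || nrow(copula) != k || ncol(copula) != k) {
    stop_param("copula must be a %d x %d matrix matching the marginals", k, k)
  }
  if (max(abs(copula - t(copula))) > 1e-8 || any(abs(diag(copula) - 1) > 1e-8)) {
    stop_param("copula must be symmetric with unit diagonal")
  }
  ev <- eigen(copula, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop_param("copula matrix is not positive semi-definite")
  set.seed(seed)

  nm <- names(marginals)
  if (n_windows == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), k), nm))
  } else {
    # eigendecomposition square root: tolerates a semi-definite copula
    ed <- eigen(copula, symmetric = TRUE)
    rt <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), k) %*% t(ed$vectors)
    z <- matrix(rnorm(n_windows * k), n_windows, k) %*% rt
    u <- pnorm(z)
    out <- as.data.frame(setNames(
      lapply(seq_len(k), function(j) .apply_marginal(u[, j], marginals[[j]])),
      nm))
  }
  attr(out, "copula") <- copula
  attr(out, "marginals") <- marginals
  attr(out, "seed") <- seed
  class(out) <- c("synthetic_window_table", "data.frame")
  out
}

.apply_marginal <- function(u, m) {
  switch(m$dist,
    gamma  = stats::qgamma(u, shape = m$shape, rate = m$rate %||% 1),
    exp    = stats::qexp(u, rate = m$rate),
    beta   = stats::qbeta(u, m$shape1, m$shape2),
    lnorm  = stats::qlnorm(u, m$meanlog %||% 0, m$sdlog %||% 1),
    norm   = stats::qnorm(u, m$mean %||% 0, m$sd %||% 1),
    unif   = stats::qunif(u, m$min %||% 0, m$max %||% 1),
    pois   = stats::qpois(u, m$lambda),
    nbinom = stats::qnbinom(u, size = m$size, mu = m$mu),
    binom  = stats::qbinom(u, size = m$size, prob = m$prob),
    stop_param("unknown marginal distribution '%s'", m$dist)
  )
}

#' Default marginals and copula for human-like 100 kb windows
#'
#' Marginals loosely emulate autosomal 100 kb windows: sex-averaged
#' recombination rates around 1.2 cM/Mb with a long right tail, GC fraction
#' near 0.41, a genic fraction piled up near zero, roughly 1% human-chimp
#' divergence over the counted bases, and low-coverage SNP yields.
#' @return `default_window_marginals()`: a named list of marginal specs;
#'   `default_window_copula()`: the matching latent correlation matrix.
#' @export
default_window_marginals <- function() {
  list(
    rec_rate   = list(dist = "gamma", shape = 1.1, rate = 0.9),   # cM/Mb
    gc         = list(dist = "beta", shape1 = 35, shape2 = 50),
    genic_frac = list(dist = "beta", shape1 = 0.5, shape2 = 1.2),
    divergence = list(dist = "nbinom", size = 30, mu = 800),
    snp_count  = list(dist = "nbinom", size = 8, mu = 60),
    covered    = list(dist = "unif", min = 2e4, max = 7e4),
    mean_maf   = list(dist = "beta", shape1 = 12, shape2 = 40)
  )
}

#' @rdname default_window_marginals
#' @export
default_window_copula <- function() {
  nm <- names(default_window_marginals())
  k <- length(nm)
  cop <- diag(k)
  dimnames(cop) <- list(nm, nm)
  link <- function(a, b, r) {
    cop[a, b] <<- r
    cop[b, a] <<- r
  }
  link("rec_rate", "gc", 0.25)
  link("rec_rate", "snp_count", 0.15)
  link("divergence", "snp_count", 0.30)
  link("divergence", "gc", 0.15)
  link("covered", "snp_count", 0.35)
  cop
}
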