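#' Sample a recombination hotspot map for a window
#'
#' Hotspots of fixed width are dropped along the window with independent
#' exponential gaps (mean `mean_spacing`) between them, mimicking the fine
#' scale of pedigree / LD genetic maps where most crossovers concentrate in
#' narrow hotspots. A fixed fraction `hotspot_mass` (default 80%) of the
#' window's total genetic map length is split among the hotspots with
#' symmetric Dirichlet(1, ..., 1) weights, and the remaining mass is split
#' among the background (non-hotspot) segments with an independent
#' symmetric Dirichlet. If no hotspot fits, all mass goes to the
#' background.
#'
#' @param window_length window length in bp.
#' @param width hotspot width in bp (default 2 kb).
#' @param mean_spacing mean inter-hotspot gap in bp (default 20 kb).
#' @param hotspot_mass fraction of recombination occurring in hotspots
#'   (default 0.8; exact in every sampled map with >= 1 hotspot).
#' @param seed optional integer seed (`NULL` continues the RNG stream).
#' @return list of class `hotspot_map`: `segments` (data frame `start`,
#'   `end`, `is_hotspot`, `mass` with masses summing to 1), `spacings`
#'   (realized inter-hotspot gaps, bp), `n_hotspots`, `hotspot_mass`
#'   (realized), `window_length`.
#' @examples
#' m <- sample_hotspot_map(1e5, seed = 1)
#' sum(m$segments$mass[m$segments$is_hotspot])   # 0.8
#' @export
sample_hotspot_map <- function(window_length = 1e5, width = 2000,
                               mean_spacing = 20000, hotspot_mass = 0.8,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (window_length <= width) stop_param("window shorter than one hotspot")
  # hotspot i starts one exponential gap after the end of hotspot i-1
  # (the first, one gap after the window start); drawn in batches
  gaps_all <- numeric(0)
  repeat {
    n_draw <- max(20, ceiling(window_length / (width + mean_spacing) * 1.4))
    gaps_all <- c(gaps_all, rexp(n_draw, 1 / mean_spacing))
    starts_all <- cumsum(gaps_all) + width * (seq_along(gaps_all) - 1)
    if (starts_all[length(starts_all)] + width > window_length) break
  }
  keep <- starts_all + width <= window_length
  starts <- starts_all[keep]
  k <- length(starts)
  gaps <- if (k >= 2) gaps_all[2:k] else numeric(0)
  seg <- NULL
  if (k == 0) {
    seg <- data.frame(start = 0, end = window_length, is_hotspot = FALSE,
                      mass = 1)
    realized_mass <- 0
  } else {
    hot <- data.frame(start = starts, end = starts + width,
                      is_hotspot = TRUE)
    bg_start <- c(0, hot$end)
    bg_end <- c(hot$start, window_length)
    bg <- data.frame(start = bg_start, end = bg_end, is_hotspot = FALSE)
    bg <- bg[bg$end > bg$start, , drop = FALSE]
    # symmetric Dirichlet(1,...,1) intensities within each mass class
    x_hot <- rgamma(k, 1)
    x_hot <- x_hot / sum(x_hot)
    x_bg <- rgamma(nrow(bg), 1)
    x_bg <- x_bg / sum(x_bg)
    hot$mass <- hotspot_mass * x_hot
    bg$mass <- (1 - hotspot_mass) * x_bg
    seg <- rbind(hot, bg)
    seg <- seg[order(seg$start), , drop = FALSE]
    rownames(seg) <- NULL
    realized_mass <- hotspot_mass
  }
  structure(list(segments = seg, spacings = gaps, n_hotspots = k,
                 hotspot_mass = realized_mass,
                 window_length = window_length),
            class = "hotspot_map")
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat(sprintf("hotspot map: %d hotspot(s) over %g bp, %.0f%% of map mass\n",
              x$n_hotspots, x$window_length, 100 * x$hotspot_mass))
  invisible(x)
}

#' Plan simulation replicates across empirical recombination-rate bins
#'
#' Matches the simulated rate distribution to an observed one: the
#' empirical per-window rates are split into `n_bins` equal-width bins,
#' each bin is represented by its midpoint rate, and the `n_total`
#' replicates are allocated to bins proportionally to bin occupancy
#' (largest-remainder rounding so the total is exact).
#'
#' @param empirical_rates observed per-window recombination rates (cM/Mb).
#' @param n_bins number of bins (default 100).
#' @param n_total total number of replicates to plan.
#' @return data frame with one row per replicate: `replicate`, `rate`
#'   (bin midpoint, cM/Mb), `bin`; bin occupancy kept as attribute `bins`.
#' @export
assign_recombination_rates <- function(empirical_rates, n_bins = 100,
                                       n_total) {
  if (any(empirical_rates < 0)) stop_param("rates must be non-negative")
  if (n_total == 0) {
    return(data.frame(replicate = integer(), rate = numeric(),
                      bin = integer()))
  }
  r <- range(empirical_rates)
  if (r[1] == r[2]) {
    breaks <- c(r[1] - 0.5, r[1] + 0.5)
  } else {
    breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  }
  bin <- findInterval(empirical_rates, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  occ <- tabulate(bin, nbins = length(breaks) - 1)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  # largest-remainder apportionment
  quota <- occ / sum(occ) * n_total
  n_rep <- floor(quota)
  rem <- n_total - sum(n_rep)
  if (rem > 0) {
    extra <- order(quota - n_rep, decreasing = TRUE)[seq_len(rem)]
    n_rep[extra] <- n_rep[extra] + 1
  }
  plan <- data.frame(
    replicate = seq_len(n_total),
    rate = rep(mids, n_rep),
    bin = rep(seq_along(mids), n_rep))
  attr(plan, "bins") <- data.frame(bin = seq_along(mids), midpoint = mids,
                                   occupancy = occ, n_replicates = n_rep)
  plan
}
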