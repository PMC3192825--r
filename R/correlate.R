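#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks use average ties; the coefficient is the Pearson correlation of
#' the ranks and the p-value comes from the t approximation with `n - 2`
#' degrees of freedom. Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list of class `correlation_result`: `rho`, `p_value`,
#'   `n_windows`, `controlled_variables`, `method`. `rho` is `NA` (with a
#'   warning) when either vector is constant.
#' @examples
#' spearman_cor(1:10, (1:10)^3)$rho  # 1: invariant to monotone transforms
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_param("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: correlation undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n_windows = n,
                          controlled_variables = character(0),
                          method = "pairwise"),
                     class = "correlation_result"))
  }
  rho <- cor(rank(x), rank(y))
  p <- .rho_t_pvalue(rho, n, n_controls = 0)
  structure(list(rho = rho, p_value = p, n_windows = n,
                 controlled_variables = character(0), method = "pairwise"),
            class = "correlation_result")
}

.rho_t_pvalue <- function(rho, n, n_controls) {
  df <- n - 2 - n_controls
  if (df <= 0 || abs(rho) >= 1) return(if (abs(rho) >= 1) 0 else NA_real_)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * pt(-abs(tstat), df)
}

#' @export
print.correlation_result <- function(x, ...) {
  ctl <- if (length(x$controlled_variables)) {
    paste(" |", paste(x$controlled_variables, collapse = ", "))
  } else ""
  cat(sprintf("%s Spearman rho = %.4f%s  (n = %d, p = %.3g)\n",
              x$method, x$rho, ctl, x$n_windows, x$p_value))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Rank-transforms every column (average ties), forms the rank correlation
#' matrix of `(x, y, controls)`, and reads the partial correlation off its
#' precision matrix: `rho_xy.Z = -Omega_xy / sqrt(Omega_xx Omega_yy)`. Only
#' complete cases are used. With no controls this reduces exactly to
#' [spearman_cor()].
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix / data frame of control variables (or
#'   `NULL`).
#' @return a `correlation_result` with `method = "partial"`.
#' @export
partial_spearman <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0) return(spearman_cor(x, y))
  controls <- as.matrix(controls)
  if (is.null(colnames(controls))) {
    colnames(controls) <- paste0("z", seq_len(ncol(controls)))
  }
  dat <- cbind(x = x, y = y, controls)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- ncol(controls)
  if (n < 3 + k) stop_param("need at least %d complete cases", 3 + k)
  ranks <- apply(dat, 2, rank)
  R <- cor(ranks)
  omega <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(omega)) {
    qr_d <- qr(R)
    bad <- colnames(R)[qr_d$pivot[seq(qr_d$rank + 1, ncol(R))]]
    stop_param("singular rank-correlation matrix; collinear variables: %s",
               paste(bad, collapse = ", "))
  }
  rho <- -omega["x", "y"] / sqrt(omega["x", "x"] * omega["y", "y"])
  structure(list(rho = rho, p_value = .rho_t_pvalue(rho, n, k),
                 n_windows = n, controlled_variables = colnames(controls),
                 method = "partial"),
            class = "correlation_result")
}

#' Permutation test for a genic vs non-genic difference in correlation
#'
#' Tests whether a correlation statistic is stronger among genic windows
#' than non-genic windows. Windows are repeatedly re-assigned at random to
#' the two groups, preserving the observed group sizes, and the difference
#' in the statistic (genic minus non-genic) is recorded. The one-sided
#' p-value is the proportion of permuted differences at least as large as
#' the observed one, by default with the add-one convention
#' `p = (#{perm >= obs} + 1) / (n_perm + 1)` so that p is never exactly 0.
#'
#' @param windows data frame with a `class` column (`"genic"` /
#'   `"nongenic"`; other classes are dropped).
#' @param statistic function taking a data frame of windows and returning a
#'   scalar (e.g. the Spearman rho of `S_norm` vs recombination rate).
#' @param n_perm number of permutations (default 10000).
#' @param sided only `"greater"` (genic > non-genic) is implemented.
#' @param seed integer seed.
#' @param add_one use the add-one p-value convention (default); `FALSE`
#'   gives the plain proportion.
#' @return list of class `permutation_test_result`: `observed_diff`,
#'   `n_perm`, `p_value`, `seed`.
#' @export
genic_permutation_test <- function(windows, statistic, n_perm = 10000,
                                   sided = "greater", seed = 1,
                                   add_one = TRUE) {
  if (n_perm < 1) stop_param("n_perm must be positive")
  stopifnot(sided == "greater")
  set.seed(seed)
  w <- windows[windows$class %in% c("genic", "nongenic"), , drop = FALSE]
  n_genic <- sum(w$class == "genic")
  n_non <- sum(w$class == "nongenic")
  if (min(n_genic, n_non) < 10) {
    warning("a group has fewer than 10 windows; ranks will be unstable")
  }
  obs <- statistic(w[w$class == "genic", , drop = FALSE]) -
    statistic(w[w$class == "nongenic", , drop = FALSE])
  n <- nrow(w)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lab <- sample.int(n, n_genic)
    perm[b] <- statistic(w[lab, , drop = FALSE]) -
      statistic(w[-lab, , drop = FALSE])
  }
  hits <- sum(perm >= obs)
  p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  structure(list(observed_diff = obs, n_perm = n_perm, p_value = p,
                 seed = seed, null_diffs = perm),
            class = "permutation_test_result")
}

#' Percentile bootstrap confidence interval for a window statistic
#'
#' Windows are resampled with replacement; a resample on which the
#' statistic is undefined (`NA`/`NaN`) is redrawn (and counted).
#'
#' @param windows data frame of windows.
#' @param statistic function from a data frame of windows to a scalar.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return numeric `c(low, high)` with attributes `n_redrawn` and `level`.
#' @export
bootstrap_ci <- function(windows, statistic, n_boot = 1000, level = 0.95,
                         seed = 1) {
  if (nrow(windows) < 30) stop_param("need at least 30 windows to bootstrap")
  set.seed(seed)
  n <- nrow(windows)
  vals <- numeric(n_boot)
  redrawn <- 0
  for (b in seq_len(n_boot)) {
    repeat {
      v <- statistic(windows[sample.int(n, n, replace = TRUE), ,
                             drop = FALSE])
      if (is.finite(v)) break
      redrawn <- redrawn + 1
      if (redrawn > 100 * n_boot) stop_param("statistic undefined on almost all resamples")
    }
    vals[b] <- v
  }
  alpha <- (1 - level) / 2
  out <- unname(quantile(vals, c(alpha, 1 - alpha)))
  attr(out, "n_redrawn") <- redrawn
  attr(out, "level") <- level
  out
}

#' Keep the windows in the top tail of a column
#'
#' @param windows data frame.
#' @param column column name (e.g. `"d_N"`).
#' @param percentile tail cut (default 0.90: windows at or above the
#'   empirical 90th percentile, i.e. the top 10%).
#' @return the qualifying rows of `windows`.
#' @export
subset_by_percentile <- function(windows, column, percentile = 0.90) {
  v <- windows[[column]]
  if (is.null(v)) stop_param("column '%s' not found", column)
  cut <- quantile(v, percentile, na.rm = TRUE)
  windows[!is.na(v) & v >= cut, , drop = FALSE]
}

#' Bin windows by a sort key and average within bins
#'
#' Sorts windows ascending by `sort_key` (ties broken by genomic
#' coordinate when `chrom`/`start` are present, otherwise by input order),
#' groups them into consecutive runs of `bin_size`, and returns per-bin
#' means of every numeric column. A trailing partial bin is kept and
#' flagged.
#'
#' @param windows data frame of windows.
#' @param sort_key column to sort by (default `"rec_rate"`).
#' @param bin_size windows per bin (default 50).
#' @return data frame of per-bin means with `bin`, `n`, and `partial`.
#' @export
bin_windows <- function(windows, sort_key = "rec_rate", bin_size = 50) {
  if (bin_size < 1) stop_param("bin_size must be >= 1")
  key <- windows[[sort_key]]
  if (is.null(key)) stop_param("column '%s' not found", sort_key)
  tie1 <- if ("chrom" %in% names(windows)) windows$chrom else
    seq_len(nrow(windows))
  tie2 <- if ("start" %in% names(windows)) windows$start else
    seq_len(nrow(windows))
  ord <- order(key, tie1, tie2)
  w <- windows[ord, , drop = FALSE]
  bin <- (seq_len(nrow(w)) - 1) %/% bin_size + 1
  num <- vapply(w, is.numeric, logical(1))
  agg <- stats::aggregate(w[, num, drop = FALSE], by = list(bin = bin),
                          FUN = mean)
  agg$n <- as.vector(table(bin))
  agg$partial <- agg$n < bin_size
  agg
}
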