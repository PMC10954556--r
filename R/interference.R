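# Crossover interference statistics: Poisson goodness of fit, dispersion
# test, and coefficient-of-coincidence curves with interval resampling.

#' Chi-squared goodness-of-fit of crossover counts to a Poisson law
#'
#' Compares the histogram of per-gamete crossover counts with the Poisson
#' expectation at the sample mean. Count bins whose expected frequency is
#' below 5 are merged into the upper tail; degrees of freedom are
#' `bins - 2` (one for the total, one for the estimated mean).
#'
#' @param counts Integer vector of per-gamete (or per-chromatid) crossover
#'   counts; at least 20 observations.
#' @return List with `statistic`, `df`, `p_value`, `lambda` and the merged
#'   observed/expected table.
#' @export
poisson_gof <- function(counts) {
  n <- length(counts)
  if (n < 20L) stop("need at least 20 counts", call. = FALSE)
  lambda <- mean(counts)
  kmax <- max(counts)
  probs <- stats::dpois(0:kmax, lambda)
  probs <- c(probs, stats::ppois(kmax, lambda, lower.tail = FALSE))
  expected <- n * probs
  obs <- c(tabulate(counts + 1L, nbins = kmax + 1L), 0)
  # merge under-populated bins into the tail, from the top down
  while (length(expected) > 2L && expected[length(expected)] < 5) {
    k <- length(expected)
    expected[k - 1L] <- expected[k - 1L] + expected[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    expected <- expected[-k]; obs <- obs[-k]
  }
  if (length(expected) < 2L) {
    stop("fewer than 2 bins after merging; counts too concentrated",
         call. = FALSE)
  }
  stat <- sum((obs - expected)^2 / expected)
  df <- length(expected) - 2L
  if (df < 1L) stop("no degrees of freedom left after merging", call. = FALSE)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       lambda = lambda,
       table = data.frame(observed = obs, expected = expected))
}

#' Variance-ratio dispersion test of crossover counts
#'
#' Tests the index of dispersion `variance / mean` against 1 using the
#' statistic `(n - 1) * variance / mean`, chi-squared with `n - 1` degrees
#' of freedom under a Poisson null. Under-dispersion (`ratio < 1` with a
#' significant two-sided p-value) is the signature of crossover
#' interference.
#'
#' @param counts Integer vector, `n >= 2`, positive mean.
#' @param alpha Significance level for the verdict.
#' @return List of class `dispersion_result`: `n`, `mean`, `variance`,
#'   `ratio`, `statistic`, `p_value`, `verdict` in
#'   `c("under", "over", "consistent")`.
#' @export
dispersion_test <- function(counts, alpha = 0.05) {
  n <- length(counts)
  if (n < 2L) stop("need at least 2 counts", call. = FALSE)
  m <- mean(counts)
  if (m <= 0) stop("mean count must be positive", call. = FALSE)
  v <- stats::var(counts)
  ratio <- v / m
  stat <- (n - 1) * ratio
  p <- 2 * min(stats::pchisq(stat, n - 1),
               stats::pchisq(stat, n - 1, lower.tail = FALSE))
  p <- min(1, p)
  verdict <- if (p < alpha && ratio < 1) "under"
             else if (p < alpha && ratio > 1) "over"
             else "consistent"
  structure(list(n = n, mean = m, variance = v, ratio = ratio,
                 statistic = stat, p_value = p, verdict = verdict),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "Dispersion test: var/mean = %.3f (n = %d), statistic = %.1f, p = %.3g -> %sdispersed\n",
    x$ratio, x$n, x$statistic, x$p_value,
    switch(x$verdict, under = "under", over = "over", "not significantly ")
  ))
  invisible(x)
}

#' Coefficient-of-coincidence curve over chromosome intervals
#'
#' Divides one chromosome into `k` equal intervals and, for every interval
#' pair `(i, j)`, computes `CoC = f_ij / (f_i * f_j)` where `f_i` is the
#' fraction of gametes with at least one crossover in interval `i` and
#' `f_ij` the fraction with crossovers in both. Because crossovers are only
#' localised to intervals between flanking markers, each crossover is
#' represented by a uniform random point within its interval, and the CoC
#' is averaged over `rounds` resampling rounds. `CoC < 1` at a given
#' separation means double crossovers are rarer than independence predicts,
#' i.e. interference.
#'
#' @param cos Crossover interval table for one chromosome (`cell_id`,
#'   `start`, `end`).
#' @param cell_ids All cell ids of the cohort.
#' @param chrom_length Chromosome length, bp.
#' @param k Number of intervals (>= 2).
#' @param rounds Resampling rounds (>= 1).
#' @param seed Integer seed.
#' @return Object of class `coc_curve`: `pairs` (data.frame `i`, `j`,
#'   `separation_bp` between interval midpoints, `coc`, `n_rounds_used`),
#'   `curve` (mean CoC by separation), `k`, `rounds`, and
#'   `n_undefined_pairs` (pairs never defined because `f_i * f_j = 0`).
#' @export
coc_curve <- function(cos, cell_ids, chrom_length, k = 15L, rounds = 100L,
                      seed = 1L) {
  .check_scalar(k, "k", lower = 2)
  .check_scalar(rounds, "rounds", lower = 1)
  k <- as.integer(k); rounds <- as.integer(rounds)
  n <- length(cell_ids)
  cell_idx <- match(cos$cell_id, cell_ids)
  if (anyNA(cell_idx)) stop("crossover cell_id not in cell_ids", call. = FALSE)
  w <- cos$end - cos$start
  bin_width <- chrom_length / k
  pair_i <- rep(seq_len(k), times = k)
  pair_j <- rep(seq_len(k), each = k)
  keep_pair <- pair_i < pair_j
  sum_coc <- matrix(0, k, k)
  n_used <- matrix(0L, k, k)
  with_seed(seed, {
    for (r in seq_len(rounds)) {
      pts <- cos$start + stats::runif(nrow(cos)) * pmax(w, 0)
      b <- pmin(k, pmax(1L, floor(pts / bin_width) + 1L))
      m <- matrix(0, n, k)
      m[cbind(cell_idx, b)] <- 1
      f <- colMeans(m)
      fij <- crossprod(m > 0) / n
      denom <- outer(f, f)
      ok <- denom > 0
      sum_coc[ok] <- sum_coc[ok] + fij[ok] / denom[ok]
      n_used <- n_used + ok
    }
  })
  coc <- ifelse(n_used > 0, sum_coc / n_used, NA_real_)
  pairs <- data.frame(
    i = pair_i[keep_pair], j = pair_j[keep_pair],
    separation_bp = (pair_j[keep_pair] - pair_i[keep_pair]) * bin_width,
    coc = coc[cbind(pair_i[keep_pair], pair_j[keep_pair])],
    n_rounds_used = n_used[cbind(pair_i[keep_pair], pair_j[keep_pair])]
  )
  defined <- !is.na(pairs$coc)
  curve <- if (any(defined)) {
    agg <- tapply(pairs$coc[defined], pairs$separation_bp[defined], mean)
    data.frame(separation_bp = as.numeric(names(agg)),
               mean_coc = as.numeric(agg))
  } else {
    data.frame(separation_bp = numeric(0), mean_coc = numeric(0))
  }
  structure(list(pairs = pairs, curve = curve, k = k, rounds = rounds,
                 n_undefined_pairs = sum(!defined)),
            class = "coc_curve")
}

#' @export
print.coc_curve <- function(x, ...) {
  cat(sprintf("<coc_curve> k = %d, %d rounds, mean CoC = %.3f (%d pairs, %d undefined)\n",
              x$k, x$rounds, mean(x$pairs$coc, na.rm = TRUE),
              nrow(x$pairs), x$n_undefined_pairs))
  invisible(x)
}
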