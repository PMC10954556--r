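# Crossover / feature association: permutation null with pseudo-crossovers,
# Z-scores, relative distance to flanking centromeric units, metagene
# profiles, and window-level correlation matrices.

#' Place pseudo-crossovers at random, preserving counts and widths
#'
#' For each simulation round and chromosome, places exactly the observed
#' number of pseudo-crossover intervals: each draws a width from the
#' empirical pool of real crossover interval widths (with replacement) and
#' a start uniform on `[0, L - width]`, so intervals always lie inside the
#' chromosome; pseudo-crossovers may overlap each other.
#'
#' @param per_chrom_counts Named integer vector: crossovers per chromosome.
#' @param gap_pool Numeric vector of observed crossover interval widths, bp.
#' @param chrom_lengths Named vector of chromosome lengths, bp.
#' @param n_rounds Number of simulation rounds (default 5000).
#' @param seed Integer seed.
#' @return Data.frame `round`, `chrom`, `start`, `end`.
#' @export
permute_pseudo_cos <- function(per_chrom_counts, gap_pool, chrom_lengths,
                               n_rounds = 5000L, seed = 1L) {
  if (!length(per_chrom_counts) || sum(per_chrom_counts) == 0) {
    stop("per_chrom_counts must contain at least one crossover", call. = FALSE)
  }
  if (!length(gap_pool)) stop("gap_pool is empty", call. = FALSE)
  .check_scalar(n_rounds, "n_rounds", lower = 1)
  chroms <- names(per_chrom_counts)
  if (is.null(chroms) || !all(chroms %in% names(chrom_lengths))) {
    stop("per_chrom_counts must be named by chromosomes in chrom_lengths",
         call. = FALSE)
  }
  max_gap <- max(gap_pool)
  for (ch in chroms[per_chrom_counts > 0]) {
    if (max_gap > chrom_lengths[[ch]]) {
      stop(sprintf("gap of %g bp exceeds length of %s", max_gap, ch),
           call. = FALSE)
    }
  }
  counts <- as.integer(per_chrom_counts)
  per_round <- sum(counts)
  total <- per_round * as.integer(n_rounds)
  chrom_vec <- rep(rep(chroms, counts), times = n_rounds)
  L <- as.numeric(chrom_lengths[chrom_vec])
  with_seed(seed, {
    len <- sample(gap_pool, total, replace = TRUE)
    start <- floor(stats::runif(total) * (L - len + 1))
    data.frame(round = rep(seq_len(n_rounds), each = per_round),
               chrom = chrom_vec, start = start, end = start + len,
               stringsAsFactors = FALSE)
  })
}

# per-round overlap counts of a pseudo-crossover table against one track
.null_counts <- function(pseudo, features, n_rounds) {
  hits <- integer(0)
  for (ch in intersect(unique(pseudo$chrom), unique(features$chrom))) {
    sel <- which(pseudo$chrom == ch)
    q <- .bed_to_iranges(pseudo[sel, , drop = FALSE])
    s <- .bed_to_iranges(features[features$chrom == ch, , drop = FALSE])
    hit <- sel[IRanges::countOverlaps(q, s) > 0L]
    hits <- c(hits, hit)
  }
  tabulate(pseudo$round[hits], nbins = n_rounds)
}

#' Z-scores of crossover/feature overlap against a permutation null
#'
#' For each feature track, counts the observed crossover intervals
#' overlapping the track, then compares with the distribution of the same
#' count over `n_rounds` pseudo-crossover placements
#' ([permute_pseudo_cos()]) that preserve per-chromosome crossover counts
#' and empirical interval widths. `Z = (observed - mean) / sd`; positive Z
#' means enrichment.
#'
#' @param cos Crossover interval table (`chrom`, `start`, `end`).
#' @param feature_tracks Named list of feature interval tables.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_rounds Permutation rounds (>= 100; default 5000).
#' @param seed Integer seed.
#' @param per_chrom_counts,gap_pool Override the null configuration
#'   (defaults are taken from `cos` itself).
#' @return Data.frame `feature`, `observed`, `null_mean`, `null_sd`, `z`
#'   (NA with a warning when the null has zero spread), with the per-round
#'   null counts in `attr(, "null_draws")`.
#' @export
z_scores <- function(cos, feature_tracks, chrom_lengths, n_rounds = 5000L,
                     seed = 1L, per_chrom_counts = NULL, gap_pool = NULL) {
  if (n_rounds < 100L) stop("n_rounds must be >= 100", call. = FALSE)
  if (is.null(per_chrom_counts)) {
    tab <- table(factor(cos$chrom, levels = names(chrom_lengths)))
    per_chrom_counts <- stats::setNames(as.integer(tab), names(tab))
  }
  if (is.null(gap_pool)) gap_pool <- pmax(cos$end - cos$start, 1)
  pseudo <- permute_pseudo_cos(per_chrom_counts, gap_pool, chrom_lengths,
                               n_rounds, seed)
  draws <- matrix(0L, nrow = n_rounds, ncol = length(feature_tracks),
                  dimnames = list(NULL, names(feature_tracks)))
  rows <- lapply(names(feature_tracks), function(lab) {
    feat <- feature_tracks[[lab]]
    obs <- overlap_count(cos, feat)
    nc <- .null_counts(pseudo, feat, n_rounds)
    draws[, lab] <<- nc
    mu <- mean(nc); sdv <- stats::sd(nc)
    z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
    if (is.na(z)) warning("null distribution for '", lab,
                          "' has zero spread; Z undefined")
    data.frame(feature = lab, observed = obs, null_mean = mu, null_sd = sdv,
               z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "null_draws") <- draws
  out
}

#' Relative distance of crossovers to flanking centromeric units
#'
#' For each crossover midpoint `p` strictly between two units, computes the
#' normalised position `r = (p - e_left) / (s_right - e_left)` where
#' `e_left` is the end of the nearest unit to the left and `s_right` the
#' start of the nearest unit to the right, so every inter-unit gap maps to
#' `[0, 1]`. Crossovers inside a unit, or outside the first/last unit of a
#' chromosome, are excluded and counted. A flat profile means proximity to
#' a centromeric unit neither attracts nor repels crossovers.
#'
#' @param cos Crossover interval table (midpoints are used).
#' @param units Sorted disjoint unit intervals (e.g. merged centromeric
#'   arrays).
#' @param n_bins Bins for the summarised profile.
#' @return List with `r` (per-crossover relative positions), `bins`
#'   (data.frame `mid`, `count`, `fit`, `se`; the fit is a span-0.75
#'   degree-1 loess, i.e. tri-cube weighted local linear regression),
#'   `n_inside`, `n_outside`.
#' @export
relative_distance_profile <- function(cos, units, n_bins = 25L) {
  r_all <- numeric(0); n_inside <- 0L; n_outside <- 0L
  for (ch in unique(cos$chrom)) {
    u <- units[units$chrom == ch, , drop = FALSE]
    if (nrow(u) < 2L) {
      warning("chromosome ", ch, " has < 2 units; skipped")
      next
    }
    u <- u[order(u$start), , drop = FALSE]
    d <- cos[cos$chrom == ch, , drop = FALSE]
    p <- (d$start + d$end) / 2
    j <- findInterval(p, u$start)
    for (ii in seq_along(p)) {
      jj <- j[ii]
      if (jj == 0L) { n_outside <- n_outside + 1L; next }
      if (p[ii] < u$end[jj]) { n_inside <- n_inside + 1L; next }
      if (jj == nrow(u)) { n_outside <- n_outside + 1L; next }
      r_all <- c(r_all, (p[ii] - u$end[jj]) / (u$start[jj + 1L] - u$end[jj]))
    }
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  cnt <- as.integer(table(cut(r_all, breaks, include.lowest = TRUE)))
  mid <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  fit <- se <- rep(NA_real_, n_bins)
  if (length(r_all) >= 10L) {
    lo <- stats::loess(cnt ~ mid, span = 0.75, degree = 1)
    pr <- stats::predict(lo, data.frame(mid = mid), se = TRUE)
    fit <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  }
  list(r = r_all,
       bins = data.frame(mid = mid, count = cnt, fit = fit, se = se),
       n_inside = n_inside, n_outside = n_outside)
}

#' Metagene profile of points over scaled feature bodies
#'
#' Bins point positions (e.g. crossover midpoints, marker positions) over
#' feature bodies scaled to `[0, 1]` plus absolute-bp flanks. For stranded
#' features (genes) the profile is orientation-aware: the 5' end (TSS) is
#' always on the left. A point within several features contributes to each.
#'
#' @param points Data.frame `chrom`, `pos` (0-based bp).
#' @param features Interval table, optional `strand` column.
#' @param n_bins Bins across the scaled body.
#' @param flank Flank width in bp on each side.
#' @param flank_bins Bins per flank.
#' @return Data.frame `bin` (1..`flank_bins + n_bins + flank_bins`),
#'   `zone` (`"upstream"`, `"body"`, `"downstream"`), `count`.
#' @export
metagene_profile <- function(points, features, n_bins = 50L, flank = 2500,
                             flank_bins = 10L) {
  if (any(features$end <= features$start)) {
    stop("degenerate features (end <= start)", call. = FALSE)
  }
  total_bins <- flank_bins + n_bins + flank_bins
  counts <- integer(total_bins)
  stranded <- "strand" %in% names(features)
  for (ch in intersect(unique(points$chrom), unique(features$chrom))) {
    p <- points$pos[points$chrom == ch]
    f <- features[features$chrom == ch, , drop = FALSE]
    q <- IRanges::IRanges(start = round(p) + 1L, width = 1L)
    s <- IRanges::IRanges(start = pmax(0, f$start - flank) + 1L,
                          end = f$end + flank)
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (h in seq_along(qh)) {
      pi <- p[qh[h]]
      fi <- sh[h]
      fs <- f$start[fi]; fe <- f$end[fi]
      minus <- stranded && f$strand[fi] == "-"
      if (pi < fs) {
        off <- (pi - (fs - flank)) / flank     # 0..1 across upstream flank
        zone <- if (minus) "down" else "up"
        frac <- if (minus) 1 - off else off
      } else if (pi >= fe) {
        off <- (pi - fe) / flank
        zone <- if (minus) "up" else "down"
        frac <- if (minus) 1 - off else off
      } else {
        zone <- "body"
        frac <- (pi - fs) / (fe - fs)
        if (minus) frac <- 1 - frac
      }
      frac <- min(max(frac, 0), 1 - 1e-12)
      b <- switch(zone,
        up = 1L + floor(frac * flank_bins),
        body = flank_bins + 1L + floor(frac * n_bins),
        down = flank_bins + n_bins + 1L + floor(frac * flank_bins)
      )
      counts[b] <- counts[b] + 1L
    }
  }
  data.frame(
    bin = seq_len(total_bins),
    zone = rep(c("upstream", "body", "downstream"),
               c(flank_bins, n_bins, flank_bins)),
    count = counts
  )
}

#' Window-level feature matrix
#'
#' Summarises tracks over sliding windows for correlation analysis. Each
#' track is either an interval table (the per-window value is the count of
#' interval midpoints) or a numeric list `list(cos =, n_cells =)` giving a
#' crossover rate track.
#'
#' @param tracks Named list of interval tables (and optionally one
#'   `list(cos =, n_cells =)` entry).
#' @param chrom_info Data.frame `name`, `length`.
#' @param window,step Window geometry in bp (defaults 1 Mb / 250 kb).
#' @return Numeric matrix, windows x tracks.
#' @export
feature_window_matrix <- function(tracks, chrom_info, window = 1e6,
                                  step = 2.5e5) {
  win <- list()
  for (i in seq_len(nrow(chrom_info))) {
    L <- chrom_info$length[i]
    if (L < window) next
    starts <- seq(0, L - window, by = step)
    win[[chrom_info$name[i]]] <- data.frame(chrom = chrom_info$name[i],
                                            start = starts,
                                            end = starts + window)
  }
  win <- do.call(rbind, win)
  if (is.null(win)) stop("no windows fit inside the chromosomes", call. = FALSE)
  vals <- sapply(tracks, function(tr) {
    if (is.data.frame(tr)) {
      mids <- (tr$start + tr$end) / 2
      vapply(seq_len(nrow(win)), function(k) {
        sum(tr$chrom == win$chrom[k] & mids >= win$start[k] &
              mids < win$end[k])
      }, 0)
    } else {
      rt <- co_rate_track(tr$cos, tr$n_cells,
                          chrom_info, window = window, step = step)
      key <- paste(rt$chrom, rt$start)
      as.numeric(rt$rate[match(paste(win$chrom, win$start), key)])
    }
  })
  rownames(vals) <- paste(win$chrom, win$start, sep = ":")
  vals
}

#' Pairwise Pearson correlation of windowed tracks
#'
#' @param mat Numeric matrix, windows x tracks (at least 3 windows), e.g.
#'   from [feature_window_matrix()].
#' @return Symmetric correlation matrix; entries of zero-variance tracks
#'   are NA, the diagonal is 1 for tracks with positive variance.
#' @export
window_correlation_matrix <- function(mat) {
  if (nrow(mat) < 3L) stop("need at least 3 windows", call. = FALSE)
  sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
  cc <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}
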