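# Centromeric-unit annotation: merging rules for tandem-repeat monomers and
# ChIP peak domains, and cross-haplotype comparison of repeat arrays via
# syntenic scaling, pairing, and a battery of classical tests.

#' Merge Tyba-like repeat monomers into centromeric arrays
#'
#' Applies, in order: (1) drop monomer annotations shorter than
#' `min_monomer` bp (spurious low-quality fragments); (2) merge adjacent
#' monomers whose gap is at most `merge_gap` (inclusive, "a maximum
#' distance of 25 kb") into one array; (3) drop merged arrays smaller than
#' `min_array` bp.
#'
#' @param monomers Interval table (`chrom`, `start`, `end`).
#' @param min_monomer,merge_gap,min_array Rule parameters in bp.
#' @return Sorted, disjoint array intervals with `width` and `midpoint`
#'   columns.
#' @export
merge_tyba <- function(monomers, min_monomer = 500, merge_gap = 25000,
                       min_array = 2000) {
  m <- monomers[monomers$end - monomers$start >= min_monomer, , drop = FALSE]
  out <- .merge_intervals(m, merge_gap, strict = FALSE)
  out <- out[out$end - out$start >= min_array, , drop = FALSE]
  out$width <- out$end - out$start
  out$midpoint <- (out$start + out$end) / 2
  rownames(out) <- NULL
  out
}

#' Merge ChIP peaks into centromeric domains
#'
#' Merges peaks whose spacing is strictly less than `merge_gap`
#' ("a spacing distance less than 25 kb"), then drops domains smaller than
#' `min_domain` bp.
#'
#' @param peaks Interval table.
#' @param merge_gap,min_domain Rule parameters in bp.
#' @return Sorted, disjoint domain intervals with `width` and `midpoint`.
#' @export
merge_cenh3 <- function(peaks, merge_gap = 25000, min_domain = 1000) {
  out <- .merge_intervals(peaks, merge_gap, strict = TRUE)
  out <- out[out$end - out$start >= min_domain, , drop = FALSE]
  out$width <- out$end - out$start
  out$midpoint <- (out$start + out$end) / 2
  rownames(out) <- NULL
  out
}

#' Pair repeat arrays between haplotypes at syntenic positions
#'
#' Assigns each array (by midpoint containment) to the syntenic block it
#' resides in, scales the midpoint to a relative position
#' `rel = (midpoint - block_start) / block_length` within that block, and
#' pairs arrays between the two haplotypes greedily by increasing
#' `|rel1 - rel2|` within corresponding blocks, one-to-one. Arrays outside
#' any block remain unpaired.
#'
#' @param h1,h2 Array tables (from [merge_tyba()]) for haplotype 1 and 2.
#' @param blocks Syntenic block map: data.frame `chrom`, `h1_start`,
#'   `h1_end`, `h2_start`, `h2_end` (0-based half-open, non-overlapping
#'   within each haplotype).
#' @return List with `pairs` (data.frame `block`, `h1_row`, `h2_row`,
#'   `rel1`, `rel2`, `drel`), `rel1_all`, `rel2_all` (relative positions of
#'   all block-assigned arrays) and `n_pairs`.
#' @export
pair_arrays <- function(h1, h2, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) {
    stop("empty syntenic block map", call. = FALSE)
  }
  assign_rel <- function(arr, bstart, bend, bchrom) {
    mid <- (arr$start + arr$end) / 2
    blk <- rep(NA_integer_, nrow(arr))
    rel <- rep(NA_real_, nrow(arr))
    for (b in seq_along(bstart)) {
      sel <- arr$chrom == bchrom[b] & mid >= bstart[b] & mid < bend[b]
      blk[sel] <- b
      rel[sel] <- (mid[sel] - bstart[b]) / (bend[b] - bstart[b])
    }
    data.frame(row = seq_len(nrow(arr)), block = blk, rel = rel)
  }
  a1 <- assign_rel(h1, blocks$h1_start, blocks$h1_end, blocks$chrom)
  a2 <- assign_rel(h2, blocks$h2_start, blocks$h2_end, blocks$chrom)
  pairs <- list(); np <- 0L
  for (b in seq_len(nrow(blocks))) {
    c1 <- a1[!is.na(a1$block) & a1$block == b, , drop = FALSE]
    c2 <- a2[!is.na(a2$block) & a2$block == b, , drop = FALSE]
    if (!nrow(c1) || !nrow(c2)) next
    cand <- expand.grid(i = seq_len(nrow(c1)), j = seq_len(nrow(c2)))
    cand$d <- abs(c1$rel[cand$i] - c2$rel[cand$j])
    cand <- cand[order(cand$d), , drop = FALSE]
    used1 <- logical(nrow(c1)); used2 <- logical(nrow(c2))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used1[i] || used2[j]) next
      used1[i] <- TRUE; used2[j] <- TRUE
      np <- np + 1L
      pairs[[np]] <- data.frame(block = b, h1_row = c1$row[i],
                                h2_row = c2$row[j], rel1 = c1$rel[i],
                                rel2 = c2$rel[j],
                                drel = c2$rel[j] - c1$rel[i])
    }
  }
  pairs <- if (np) do.call(rbind, pairs) else
    data.frame(block = integer(0), h1_row = integer(0), h2_row = integer(0),
               rel1 = numeric(0), rel2 = numeric(0), drel = numeric(0))
  rownames(pairs) <- NULL
  list(pairs = pairs,
       rel1_all = a1$rel[!is.na(a1$rel)],
       rel2_all = a2$rel[!is.na(a2$rel)],
       n_pairs = np)
}

.try_test <- function(expr) {
  tryCatch(expr, error = function(e) {
    list(statistic = NA_real_, p.value = NA_real_, reason = conditionMessage(e))
  })
}

#' Cross-haplotype comparison of repeat arrays
#'
#' Runs the classical battery comparing centromeric arrays between two
#' haplotypes: Shapiro-Wilk normality of per-chromosome array counts,
#' two-sided F-test of count variances, two-sided t-test of count means,
#' Mann-Whitney U-test of array sizes, two-sample Kolmogorov-Smirnov test
#' of relative (syntenic-block-scaled) midpoint positions, and a linear
#' regression of the relative-position differences of paired arrays against
#' position (structural conservation shows as slope and intercept near 0).
#'
#' @param h1,h2 Array tables.
#' @param pairing Result of [pair_arrays()].
#' @return Named list of test results; tests that cannot run (insufficient
#'   n) return NA statistics with a `reason`.
#' @export
compare_array_stats <- function(h1, h2, pairing) {
  counts1 <- as.integer(table(h1$chrom))
  counts2 <- as.integer(table(h2$chrom))
  res <- list(
    shapiro_h1 = .try_test(stats::shapiro.test(counts1)),
    shapiro_h2 = .try_test(stats::shapiro.test(counts2)),
    f_test = .try_test(stats::var.test(counts1, counts2)),
    t_test = .try_test(stats::t.test(counts1, counts2, var.equal = TRUE)),
    mann_whitney_size = .try_test(
      stats::wilcox.test(h1$end - h1$start, h2$end - h2$start)
    ),
    ks_position = .try_test(
      suppressWarnings(stats::ks.test(pairing$rel1_all, pairing$rel2_all))
    )
  )
  if (nrow(pairing$pairs) >= 3L) {
    fit <- stats::lm(drel ~ rel1, data = pairing$pairs)
    co <- summary(fit)$coefficients
    res$regression <- list(intercept = co[1, 1], slope = co[2, 1],
                           p_intercept = co[1, 4], p_slope = co[2, 4])
  } else {
    res$regression <- list(intercept = NA_real_, slope = NA_real_,
                           reason = "fewer than 3 pairs")
  }
  res
}
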