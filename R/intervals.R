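# Interval utilities. All genomic intervals in this package are BED-style:
# 0-based, half-open [start, end). Marker positions are 1-based to match VCF.

#' Construct a BED-style interval table
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open.
#' @param ... Further columns (e.g. `strand`, `name`), recycled by
#'   `data.frame()`.
#' @return A `data.frame` sorted by `(chrom, start)`.
#' @export
bed <- function(chrom, start, end, ...) {
  if (any(end < start)) stop("interval end < start", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Convert half-open 0-based intervals to IRanges (1-based closed). Zero-width
# intervals become 1 bp points so they can still participate in overlaps.
.bed_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L))
}

#' Count intervals overlapping a feature track
#'
#' Counts how many query intervals intersect (by at least 1 bp, half-open
#' convention) at least one interval of `features`. Each query interval is
#' counted at most once, mirroring `bedtools intersect -u`.
#'
#' @param cos Interval table (`chrom`, `start`, `end`), e.g. crossover
#'   intervals.
#' @param features Interval table of the feature track.
#' @return Integer count.
#' @export
overlap_count <- function(cos, features) {
  if (nrow(cos) == 0L || nrow(features) == 0L) return(0L)
  total <- 0L
  for (ch in intersect(unique(cos$chrom), unique(features$chrom))) {
    q <- .bed_to_iranges(cos[cos$chrom == ch, , drop = FALSE])
    s <- .bed_to_iranges(features[features$chrom == ch, , drop = FALSE])
    total <- total + sum(IRanges::countOverlaps(q, s) > 0L)
  }
  total
}

# Merge sorted intervals whose inter-interval gap passes the rule.
# strict = FALSE: merge when gap <= max_gap; strict = TRUE: merge when
# gap < max_gap. Overlapping/adjacent intervals (gap <= 0) always merge.
.merge_intervals <- function(df, max_gap, strict = FALSE) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- lapply(split(df, df$chrom), function(d) {
    # running maximum of end handles contained intervals
    hi <- cummax(d$end)
    gap <- d$start - c(-Inf, hi[-nrow(d)])
    new_grp <- if (strict) gap >= max_gap else gap > max_gap
    grp <- cumsum(new_grp)
    data.frame(
      chrom = d$chrom[1L],
      start = tapply(d$start, grp, min),
      end = tapply(d$end, grp, max),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
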