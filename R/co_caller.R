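# Two-stage smoothing genotyper for sparse gamete markers and crossover
# interval calling between qualified genotype blocks.

#' Crossover-caller parameters
#'
#' @param window_af Half-width of the allele-frequency smoothing window
#'   (markers ahead and behind; default 2, i.e. a 5-marker window).
#' @param window_gt Half-width of the genotype majority-vote window.
#' @param min_block_markers Minimum markers for a block to be qualified.
#' @param block_span_bp A block qualifies only if some `min_block_markers`
#'   consecutive member markers span at most this many bp (default 1 Mb).
#' @param min_double_co_sep Consecutive crossovers on one chromatid closer
#'   than this (midpoint distance, bp) are flagged `close_double_co`.
#' @param double_co_rescue_markers A flagged close pair is kept only when
#'   every flanking qualified block group involved has at least this many
#'   markers; otherwise both calls are dropped (automated surrogate for
#'   manual double-crossover review).
#' @param drop_close_doubles Apply the drop policy (default `TRUE`); when
#'   `FALSE` flagged calls are retained.
#' @return List of class `co_params`.
#' @export
co_params <- function(window_af = 2L, window_gt = 2L,
                      min_block_markers = 5L, block_span_bp = 1e6,
                      min_double_co_sep = 2e6,
                      double_co_rescue_markers = 10L,
                      drop_close_doubles = TRUE) {
  .check_scalar(window_af, "window_af", lower = 0)
  .check_scalar(window_gt, "window_gt", lower = 0)
  .check_scalar(min_block_markers, "min_block_markers", lower = 1)
  .check_scalar(block_span_bp, "block_span_bp", lower = 0, strict_lower = TRUE)
  structure(list(window_af = as.integer(window_af),
                 window_gt = as.integer(window_gt),
                 min_block_markers = as.integer(min_block_markers),
                 block_span_bp = block_span_bp,
                 min_double_co_sep = min_double_co_sep,
                 double_co_rescue_markers = as.integer(double_co_rescue_markers),
                 drop_close_doubles = isTRUE(drop_close_doubles)),
            class = "co_params")
}

#' Smooth per-marker allele frequencies over neighbouring markers
#'
#' Replaces each marker's allele frequency by the mean over the window of
#' `window` markers ahead and behind (truncated at chromosome ends), so an
#' isolated mis-read marker is absorbed by its neighbours.
#'
#' @param af Numeric vector of raw allele frequencies
#'   (`hap2 / (hap1 + hap2)`), ordered by position within one chromosome.
#' @param window Markers ahead and behind (default 2).
#' @return Numeric vector of smoothed frequencies.
#' @export
smooth_allele_frequencies <- function(af, window = 2L) {
  n <- length(af)
  if (n == 0L) return(numeric(0))
  i <- seq_len(n)
  lo <- pmax(1L, i - window)
  hi <- pmin(n, i + window)
  cs <- c(0, cumsum(af))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# genotype from (smoothed) allele frequency: H1 below 0.5, H2 above,
# NA at exactly 0.5 or undefined
.genotype_from_af <- function(af) {
  out <- rep(NA_character_, length(af))
  out[!is.na(af) & af < 0.5] <- "H1"
  out[!is.na(af) & af > 0.5] <- "H2"
  out
}

#' Smooth genotypes by neighbourhood majority vote
#'
#' Each marker's genotype is replaced by the majority genotype over the
#' window of `window` markers ahead and behind (itself included, NAs
#' excluded from the vote); ties keep the marker's own genotype.
#'
#' @param gt Character vector of genotypes (`"H1"`, `"H2"`, `NA`), ordered
#'   by position within one chromosome.
#' @param window Markers ahead and behind (default 2).
#' @return Character vector of smoothed genotypes.
#' @export
smooth_genotypes <- function(gt, window = 2L) {
  n <- length(gt)
  if (n == 0L) return(character(0))
  i <- seq_len(n)
  lo <- pmax(1L, i - window)
  hi <- pmin(n, i + window)
  c1 <- c(0L, cumsum(!is.na(gt) & gt == "H1"))
  c2 <- c(0L, cumsum(!is.na(gt) & gt == "H2"))
  n1 <- c1[hi + 1L] - c1[lo]
  n2 <- c2[hi + 1L] - c2[lo]
  out <- gt
  out[n1 > n2] <- "H1"
  out[n2 > n1] <- "H2"
  # ties (including all-NA windows) keep the marker's own genotype
  out
}

#' Build genotype blocks from smoothed genotypes
#'
#' Maximal runs of markers sharing the same non-NA smoothed genotype become
#' blocks (NA markers are skipped and do not interrupt a run). A block is
#' qualified to carry genotype state when it contains at least
#' `min_markers` markers of which some `min_markers` consecutive ones span
#' at most `span_bp`, i.e. a locally dense core; long dense blocks always
#' qualify, sparse spurious runs do not.
#'
#' @param pos Marker positions (1-based), sorted, one chromosome.
#' @param gt Smoothed genotypes aligned with `pos`.
#' @param min_markers,span_bp Qualification rule (defaults 5 markers within
#'   1 Mb).
#' @return Data.frame with one row per block: `start_pos`, `end_pos` (first
#'   and last member marker positions), `genotype`, `n_markers`,
#'   `qualified`.
#' @export
build_blocks <- function(pos, gt, min_markers = 5L, span_bp = 1e6) {
  keep <- !is.na(gt)
  pos <- pos[keep]; gt <- gt[keep]
  if (!length(pos)) {
    return(data.frame(start_pos = numeric(0), end_pos = numeric(0),
                      genotype = character(0), n_markers = integer(0),
                      qualified = logical(0)))
  }
  r <- rle(gt)
  endi <- cumsum(r$lengths)
  starti <- endi - r$lengths + 1L
  qual <- vapply(seq_along(r$lengths), function(b) {
    p <- pos[starti[b]:endi[b]]
    n <- length(p)
    if (n < min_markers) return(FALSE)
    any(p[min_markers:n] - p[1:(n - min_markers + 1L)] <= span_bp)
  }, logical(1))
  data.frame(start_pos = pos[starti], end_pos = pos[endi],
             genotype = r$values, n_markers = r$lengths,
             qualified = qual, stringsAsFactors = FALSE)
}

#' Call crossover intervals from genotype blocks
#'
#' Unqualified blocks carry no genotype state: consecutive qualified blocks
#' of the same genotype merge logically (no crossover), while a genotype
#' conversion between qualified block groups yields one crossover interval
#' bracketed by the last marker of the upstream group and the first marker
#' of the downstream group. Consecutive crossovers closer than
#' `min_double_co_sep` (interval midpoints) are flagged `close_double_co`
#' and, under the default policy, both dropped unless all flanking block
#' groups have at least `double_co_rescue_markers` markers.
#'
#' @param blocks Data.frame from [build_blocks()].
#' @param chrom Chromosome name for the emitted intervals.
#' @param cell_id Cell barcode for the emitted intervals.
#' @param params A [co_params()].
#' @return Data.frame `cell_id`, `chrom`, `start`, `end` (0-based
#'   half-open, spanning the inter-marker gap), `left_markers`,
#'   `right_markers` (marker support of the flanking groups) and
#'   `close_double_co`.
#' @export
call_crossovers <- function(blocks, chrom = "chr", cell_id = "cell",
                            params = co_params()) {
  empty <- data.frame(cell_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      left_markers = integer(0), right_markers = integer(0),
                      close_double_co = logical(0))
  q <- blocks[blocks$qualified, , drop = FALSE]
  if (nrow(q) == 0L) {
    warning("no qualified genotype blocks on ", chrom, "; no calls")
    return(empty)
  }
  # merge consecutive qualified blocks with equal genotype into groups
  r <- rle(q$genotype)
  endi <- cumsum(r$lengths)
  starti <- endi - r$lengths + 1L
  grp <- data.frame(
    genotype = r$values,
    start_pos = q$start_pos[starti],
    end_pos = q$end_pos[endi],
    n_markers = vapply(seq_along(starti), function(b) {
      sum(q$n_markers[starti[b]:endi[b]])
    }, 0L)
  )
  if (nrow(grp) < 2L) return(empty)
  n_co <- nrow(grp) - 1L
  left <- grp$end_pos[seq_len(n_co)]
  right <- grp$start_pos[seq_len(n_co) + 1L]
  cos <- data.frame(
    cell_id = cell_id, chrom = chrom,
    start = left, end = pmax(right - 1, left + 1),
    left_markers = grp$n_markers[seq_len(n_co)],
    right_markers = grp$n_markers[seq_len(n_co) + 1L],
    close_double_co = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_co >= 2L && is.finite(params$min_double_co_sep)) {
    mid <- (cos$start + cos$end) / 2
    close_pair <- which(diff(mid) < params$min_double_co_sep)
    drop <- logical(n_co)
    for (p in close_pair) {
      cos$close_double_co[c(p, p + 1L)] <- TRUE
      # all three flanking qualified groups must be well supported
      support <- grp$n_markers[p:(p + 2L)]
      if (params$drop_close_doubles &&
          any(support < params$double_co_rescue_markers)) {
        drop[c(p, p + 1L)] <- TRUE
      }
    }
    cos <- cos[!drop, , drop = FALSE]
  }
  rownames(cos) <- NULL
  cos
}

#' Genotype one cell and call its crossovers
#'
#' Per chromosome: allele frequencies `hap2 / (hap1 + hap2)` are smoothed
#' over neighbouring markers, genotypes are assigned from the smoothed
#' frequencies and smoothed again by neighbourhood majority, genotype
#' blocks are built and qualified, and crossover intervals are emitted at
#' genotype conversions between qualified block groups.
#'
#' @param cell_obs Observation rows of one cell (`chrom`, `pos`,
#'   `hap1_reads`, `hap2_reads`).
#' @param params A [co_params()].
#' @param quiet Suppress the no-qualified-block warning (used by cohort
#'   wrappers).
#' @return List with `blocks` (all chromosomes), `cos` (crossover interval
#'   table) and `n_co`.
#' @export
genotype_cell <- function(cell_obs, params = co_params(), quiet = FALSE) {
  cell_id <- if (nrow(cell_obs)) cell_obs$cell_id[1] else "cell"
  blocks_out <- list(); cos_out <- list()
  for (ch in unique(cell_obs$chrom)) {
    d <- cell_obs[cell_obs$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    af <- d$hap2_reads / (d$hap1_reads + d$hap2_reads)
    saf <- smooth_allele_frequencies(af, params$window_af)
    gt <- .genotype_from_af(saf)
    gt <- smooth_genotypes(gt, params$window_gt)
    bl <- build_blocks(d$pos, gt, params$min_block_markers,
                       params$block_span_bp)
    if (nrow(bl)) bl <- cbind(chrom = ch, bl, stringsAsFactors = FALSE)
    blocks_out[[ch]] <- bl
    cc <- if (quiet) {
      suppressWarnings(call_crossovers(bl, ch, cell_id, params))
    } else {
      call_crossovers(bl, ch, cell_id, params)
    }
    cos_out[[ch]] <- cc
  }
  blocks <- do.call(rbind, blocks_out)
  cos <- do.call(rbind, cos_out)
  if (is.null(cos)) {
    cos <- data.frame(cell_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      left_markers = integer(0), right_markers = integer(0),
                      close_double_co = logical(0))
  }
  rownames(cos) <- NULL
  list(blocks = blocks, cos = cos, n_co = nrow(cos))
}

#' Call crossovers for a whole cohort
#'
#' Applies [genotype_cell()] to every cell of a long-format observation
#' table.
#'
#' @param observations Long-format observation table.
#' @param params A [co_params()].
#' @return List with `cos` (all crossover intervals), `per_cell`
#'   (data.frame `cell_id`, `n_co`).
#' @export
call_crossovers_cohort <- function(observations, params = co_params()) {
  cells <- unique(observations$cell_id)
  idx <- split(seq_len(nrow(observations)),
               factor(observations$cell_id, levels = cells))
  cos_list <- vector("list", length(cells))
  n_co <- integer(length(cells))
  for (k in seq_along(cells)) {
    res <- genotype_cell(observations[idx[[k]], , drop = FALSE], params,
                         quiet = TRUE)
    cos_list[[k]] <- res$cos
    n_co[k] <- res$n_co
  }
  cos <- do.call(rbind, cos_list)
  rownames(cos) <- NULL
  list(cos = cos, per_cell = data.frame(cell_id = cells, n_co = n_co,
                                        stringsAsFactors = FALSE))
}
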