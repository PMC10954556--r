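# Cell-level quality control: read/marker-count filters, species assignment
# from dual-reference alignment rates, and switch-rate doublet screening.

#' Partition cells by read and marker counts
#'
#' A cell is kept when its total read count is strictly greater than
#' `min_reads` (mirroring a "barcodes seen more than N times" rule) and its
#' marker count is at least `min_markers` ("fewer than N markers discarded",
#' so a cell with exactly `min_markers` is kept).
#'
#' @param observations Long-format observation table (`cell_id`, `chrom`,
#'   `pos`, `hap1_reads`, `hap2_reads`).
#' @param min_reads Strict lower bound on per-cell total reads.
#' @param min_markers Inclusive lower bound on per-cell marker count.
#' @return List with `kept` and `discarded` (character vectors of cell ids)
#'   and `report`, a per-cell data.frame of counts and pass flags.
#' @export
filter_cells <- function(observations, min_reads = 5000, min_markers = 400) {
  .check_scalar(min_reads, "min_reads", lower = 0)
  .check_scalar(min_markers, "min_markers", lower = 0)
  cells <- unique(observations$cell_id)
  f <- factor(observations$cell_id, levels = cells)
  n_markers <- as.integer(table(f))
  n_reads <- as.numeric(tapply(
    observations$hap1_reads + observations$hap2_reads, f, sum,
    default = 0
  ))
  pass_reads <- n_reads > min_reads
  pass_markers <- n_markers >= min_markers
  report <- data.frame(cell_id = cells, n_markers = n_markers,
                       n_reads = n_reads, pass_reads = pass_reads,
                       pass_markers = pass_markers,
                       kept = pass_reads & pass_markers,
                       stringsAsFactors = FALSE)
  list(kept = cells[report$kept], discarded = cells[!report$kept],
       report = report)
}

#' Assign cells to species by dual-reference alignment rates
#'
#' Cells from a mixed two-species library are labelled by comparing their
#' alignment rates against the two reference genomes: `ambiguous` when the
#' rates differ by less than `ambiguity_delta` percentage points (putative
#' cross-species doublets), otherwise the higher-rate species, downgraded to
#' `low_rate` when the winning rate is below `min_rate` percent.
#'
#' @param rates Data.frame with columns `cell_id`, `rate_A`, `rate_B`
#'   (percentages in `[0, 100]`).
#' @param min_rate Minimum winning alignment rate, percent.
#' @param ambiguity_delta Rate difference below which a cell is ambiguous,
#'   percentage points.
#' @return `rates` with an added `species_call` column taking values
#'   `"A"`, `"B"`, `"ambiguous"`, `"low_rate"`.
#' @export
assign_species <- function(rates, min_rate = 25, ambiguity_delta = 10) {
  if (any(rates$rate_A < 0 | rates$rate_A > 100 |
          rates$rate_B < 0 | rates$rate_B > 100, na.rm = TRUE)) {
    stop("alignment rates must be percentages in [0, 100]", call. = FALSE)
  }
  winner <- ifelse(rates$rate_A >= rates$rate_B, "A", "B")
  win_rate <- pmax(rates$rate_A, rates$rate_B)
  call <- ifelse(abs(rates$rate_A - rates$rate_B) < ambiguity_delta,
                 "ambiguous",
                 ifelse(win_rate < min_rate, "low_rate", winner))
  rates$species_call <- call
  rates
}

# raw per-marker genotype before any smoothing: majority of haplotype reads,
# NA on ties
.raw_genotype <- function(h1, h2) {
  ifelse(h1 > h2, "H1", ifelse(h2 > h1, "H2", NA_character_))
}

#' Genotype switch rate of one cell
#'
#' The switch rate is the number of adjacent observed-marker pairs (within
#' chromosomes, never across chromosome boundaries) whose raw majority
#' genotypes differ, divided by the total number of observed markers.
#' Markers with tied read counts carry no genotype and are skipped when
#' pairing neighbours but still count in the denominator. Cells with
#' elevated switch rates are barcode doublets: two gametes with independent
#' haplotype mosaics interleave and produce spurious alternations.
#'
#' @param cell_obs Observation rows of a single cell.
#' @param threshold Doublet cut: a cell is flagged iff rate is strictly
#'   greater than `threshold`.
#' @return List with `rate` (NA when fewer than 2 markers), `n_switches`,
#'   `n_markers` and `doublet` (fail-open: `FALSE` when rate is NA).
#' @export
switch_rate <- function(cell_obs, threshold = 0.07) {
  n_mark <- nrow(cell_obs)
  if (n_mark < 2L) {
    return(list(rate = NA_real_, n_switches = NA_integer_,
                n_markers = n_mark, doublet = FALSE))
  }
  cell_obs <- cell_obs[order(cell_obs$chrom, cell_obs$pos), , drop = FALSE]
  g <- .raw_genotype(cell_obs$hap1_reads, cell_obs$hap2_reads)
  switches <- 0L
  for (ch in unique(cell_obs$chrom)) {
    gc <- g[cell_obs$chrom == ch]
    gc <- gc[!is.na(gc)]
    if (length(gc) >= 2L) switches <- switches + sum(gc[-1L] != gc[-length(gc)])
  }
  rate <- switches / n_mark
  list(rate = rate, n_switches = as.integer(switches), n_markers = n_mark,
       doublet = !is.na(rate) && rate > threshold)
}

#' Switch rates for a cohort
#'
#' @param observations Long-format observation table.
#' @param threshold Doublet cut, as in [switch_rate()].
#' @return Data.frame `cell_id`, `n_markers`, `n_switches`, `switch_rate`,
#'   `doublet`.
#' @export
switch_rates <- function(observations, threshold = 0.07) {
  cells <- unique(observations$cell_id)
  idx <- split(seq_len(nrow(observations)),
               factor(observations$cell_id, levels = cells))
  rows <- lapply(cells, function(cid) {
    s <- switch_rate(observations[idx[[cid]], , drop = FALSE], threshold)
    data.frame(cell_id = cid, n_markers = s$n_markers,
               n_switches = s$n_switches %||% NA_integer_,
               switch_rate = s$rate, doublet = s$doublet,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
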