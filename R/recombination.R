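# Windowed recombination rates, marker thinning, Marey maps and crossover
# count distributions.

#' Windowed recombination rate track
#'
#' Computes the recombination rate in cM/Mb over sliding windows. The mass
#' of each crossover interval is spread uniformly over the interval (a
#' point crossover contributes its indicator), so
#' `rate(w) = 100 * sum(overlap_fraction) / n_cells / (window / 1 Mb)`.
#' Windows are laid from the confident-region start at fixed `step`; only
#' windows fully inside the confident region are emitted.
#'
#' @param cos Crossover interval table (`chrom`, `start`, `end`).
#' @param n_cells Number of gametes the crossovers were called in (>= 1).
#' @param chrom_info Data.frame `name`, `length`, optional `conf_start`,
#'   `conf_end` (default the full chromosome).
#' @param window,step Window and step size in bp (defaults 1 Mb / 100 kb).
#' @return Data.frame `chrom`, `start`, `end`, `rate` (cM/Mb) of class
#'   `recombination_track`.
#' @export
co_rate_track <- function(cos, n_cells, chrom_info, window = 1e6,
                          step = 1e5) {
  .check_scalar(n_cells, "n_cells", lower = 1)
  if (is.null(chrom_info$conf_start)) chrom_info$conf_start <- 0
  if (is.null(chrom_info$conf_end)) chrom_info$conf_end <- chrom_info$length
  out <- list()
  for (i in seq_len(nrow(chrom_info))) {
    ch <- chrom_info$name[i]
    a0 <- chrom_info$conf_start[i]
    b0 <- chrom_info$conf_end[i]
    if (b0 - a0 < window) next
    starts <- seq(a0, b0 - window, by = step)
    d <- cos[cos$chrom == ch, , drop = FALSE]
    mass <- numeric(length(starts))
    if (nrow(d)) {
      w <- d$end - d$start
      for (k in seq_along(starts)) {
        a <- starts[k]; b <- a + window
        ov <- pmin(d$end, b) - pmax(d$start, a)
        frac <- ifelse(w > 0, pmax(ov, 0) / w,
                       as.numeric(d$start >= a & d$start < b))
        mass[k] <- sum(frac)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + window,
                            rate = 100 * mass / n_cells / (window / 1e6),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), rate = numeric(0))
  }
  rownames(res) <- NULL
  class(res) <- c("recombination_track", class(res))
  res
}

#' Thin markers by window medians
#'
#' Selects one marker per non-empty window of `window` bp (step equal to
#' the window, from the first present marker to the last): the median
#' marker by index, taking the lower median on even counts.
#'
#' @param pos Sorted marker positions on one chromosome.
#' @param window Window size in bp (default 500 kb).
#' @return The selected marker positions.
#' @export
thin_markers <- function(pos, window = 5e5) {
  if (!length(pos)) return(pos)
  if (is.unsorted(pos)) stop("positions must be sorted", call. = FALSE)
  bin <- floor((pos - pos[1]) / window)
  idx <- split(seq_along(pos), bin)
  sel <- vapply(idx, function(ii) ii[floor((length(ii) + 1L) / 2L)], 0L)
  pos[sort(sel)]
}

#' Marey map and genetic map lengths from crossover intervals
#'
#' The genetic position at physical coordinate `x` is the expected number
#' of crossovers to the left of `x` per gamete, in cM:
#' `100 / n_cells * sum over crossovers of P(uniform point of interval < x)`.
#' The chromosome map length is the value at the chromosome end, so the
#' total map length equals `100 *` mean crossovers per gamete exactly.
#'
#' @param cos Crossover interval table.
#' @param n_cells Number of gametes.
#' @param positions Named list (per chromosome) of physical positions at
#'   which to evaluate the map, e.g. thinned markers.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Object of class `genetic_map`: list with `map` (per-chromosome
#'   data.frame `pos`, `cM`), `chrom_length_cM`, `total_cM`.
#' @export
marey_map <- function(cos, n_cells, positions, chrom_lengths) {
  .check_scalar(n_cells, "n_cells", lower = 1)
  maps <- list()
  len_cM <- stats::setNames(numeric(length(positions)), names(positions))
  for (ch in names(positions)) {
    d <- cos[cos$chrom == ch, , drop = FALSE]
    p <- sort(positions[[ch]])
    gen <- function(x) {
      if (!nrow(d)) return(0)
      w <- d$end - d$start
      fl <- ifelse(w > 0, pmin(pmax((x - d$start) / w, 0), 1),
                   as.numeric(d$start < x))
      100 * sum(fl) / n_cells
    }
    cM <- vapply(p, gen, 0)
    maps[[ch]] <- data.frame(pos = p, cM = cM)
    len_cM[[ch]] <- gen(chrom_lengths[[ch]])
  }
  structure(list(map = maps, chrom_length_cM = len_cM,
                 total_cM = sum(len_cM)), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> total %.1f cM over %d chromosomes\n",
              x$total_cM, length(x$chrom_length_cM)))
  print(round(x$chrom_length_cM, 2))
  invisible(x)
}

#' Per-gamete and per-chromatid crossover count distributions
#'
#' @param cos Crossover interval table with `cell_id`, `chrom`.
#' @param cell_ids All cell ids of the cohort (cells without crossovers
#'   contribute zero counts).
#' @param chrom_names All chromosome names.
#' @return List with `per_gamete` (data.frame `cell_id`, `n_co`),
#'   `per_chromatid` (cell x chromosome counts, long), `mean_per_gamete`,
#'   `mean_per_chromatid`, and `chromatid_fractions` (fraction of
#'   chromatids with 0, 1 and 2+ crossovers).
#' @export
co_count_distribution <- function(cos, cell_ids, chrom_names) {
  fc <- factor(cos$cell_id, levels = cell_ids)
  fch <- factor(cos$chrom, levels = chrom_names)
  per_gamete <- data.frame(cell_id = cell_ids,
                           n_co = as.integer(table(fc)),
                           stringsAsFactors = FALSE)
  tab <- table(fc, fch)
  per_chromatid <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(per_chromatid) <- c("cell_id", "chrom", "n_co")
  counts <- as.vector(tab)
  list(
    per_gamete = per_gamete,
    per_chromatid = per_chromatid,
    mean_per_gamete = mean(per_gamete$n_co),
    mean_per_chromatid = mean(counts),
    chromatid_fractions = c(
      `0` = mean(counts == 0), `1` = mean(counts == 1),
      `2+` = mean(counts >= 2)
    )
  )
}
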