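# Synthetic phased reference: chromosomes, haplotype-diagnostic SNP markers
# and feature tracks (centromeric repeat arrays, their ChIP domains, genes,
# TEs) with the geometry of a small holocentric plant genome.

#' Configuration for a synthetic phased reference genome
#'
#' Defaults emulate the study system at reduced scale: five chromosomes,
#' haplotype-specific SNP markers at ~1 per 449 bp, and centromeric
#' repeat arrays averaging ~20 kb placed every ~400 kb along the whole
#' chromosome (repeat-based holocentromeres). Chromosome lengths default to
#' 2 Mb so that simulated cohorts stay desk-sized; all densities are per-bp
#' and therefore scale-free.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length(s) in bp, recycled to `n_chrom`.
#' @param marker_spacing Mean spacing between SNP markers, bp.
#' @param tyba_size Mean centromeric (Tyba) array size, bp.
#' @param tyba_spacing Mean start-to-start spacing of arrays, bp.
#' @param genes_per_mb,gene_size Gene track density and mean width.
#' @param tes_per_mb,te_size TE track density and mean width.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(n_chrom = 5L, chrom_length = 2e6,
                          marker_spacing = 449,
                          tyba_size = 2e4, tyba_spacing = 4e5,
                          genes_per_mb = 30, gene_size = 3e3,
                          tes_per_mb = 40, te_size = 5e3) {
  .check_scalar(n_chrom, "n_chrom", lower = 1)
  if (any(chrom_length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  .check_scalar(marker_spacing, "marker_spacing", lower = 0, strict_lower = TRUE)
  .check_scalar(tyba_size, "tyba_size", lower = 0, strict_lower = TRUE)
  .check_scalar(tyba_spacing, "tyba_spacing", lower = 0, strict_lower = TRUE)
  .check_scalar(genes_per_mb, "genes_per_mb", lower = 0)
  .check_scalar(tes_per_mb, "tes_per_mb", lower = 0)
  structure(list(
    n_chrom = as.integer(n_chrom),
    chrom_length = rep_len(as.numeric(chrom_length), n_chrom),
    marker_spacing = marker_spacing,
    tyba_size = tyba_size, tyba_spacing = tyba_spacing,
    genes_per_mb = genes_per_mb, gene_size = gene_size,
    tes_per_mb = tes_per_mb, te_size = te_size
  ), class = "genome_config")
}

.BASES <- c("A", "C", "G", "T")

# Fragment one array interval into tandem monomers with sub-25 kb gaps, plus
# the occasional spurious short (<500 bp) fragment that the annotation
# merge rules are expected to discard.
.fragment_array <- function(chrom, a_start, a_end) {
  starts <- ends <- numeric(0)
  pos <- a_start
  while (pos < a_end) {
    len <- round(stats::runif(1, 800, 1600))
    starts <- c(starts, pos)
    ends <- c(ends, min(pos + len, a_end))
    pos <- pos + len + round(stats::runif(1, 0, 150))
  }
  if (stats::runif(1) < 0.3) {
    # spurious stray monomer near (but outside) the array
    s <- a_end + round(stats::runif(1, 1e3, 2e4))
    starts <- c(starts, s)
    ends <- c(ends, s + round(stats::runif(1, 150, 450)))
  }
  data.frame(chrom = chrom, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Simulate a phased reference genome with markers and feature tracks
#'
#' Generates, deterministically for a given seed, an ordered set of
#' haplotype-diagnostic SNP markers per chromosome (positions strictly
#' increasing, haplotype alleles always different) and feature tracks:
#' `tyba_arrays` (true centromeric arrays), `tyba_monomers` (the arrays
#' fragmented into tandem monomers with small gaps and occasional spurious
#' short fragments, as raw repeat annotation would produce), `cenh3_peaks`
#' (ChIP-like peaks covering the arrays, possibly split), stranded `genes`
#' and `tes`. Marker counts are `round(length / marker_spacing)` and array
#' counts `floor(length / tyba_spacing)`, so realised densities match the
#' configuration closely on chromosomes of 1 Mb and larger.
#'
#' @param config A [genome_config()].
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return An object of class `sim_genome`: list with `chromosomes`
#'   (data.frame `name`, `length`), `markers` (named list of data.frames
#'   `pos`, `hap1`, `hap2`; `pos` 1-based) and `features` (named list of
#'   BED-style tables).
#' @export
simulate_reference <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, {
    chroms <- data.frame(
      name = paste0("chr", seq_len(config$n_chrom)),
      length = config$chrom_length,
      stringsAsFactors = FALSE
    )
    markers <- list()
    tyba <- mono <- cenh3 <- genes <- tes <- list()
    for (i in seq_len(config$n_chrom)) {
      L <- chroms$length[i]
      ch <- chroms$name[i]

      n_mark <- max(1L, round(L / config$marker_spacing))
      pos <- sort(sample.int(L, min(n_mark, L)))
      hap1 <- sample(.BASES, length(pos), replace = TRUE)
      shift <- sample.int(3L, length(pos), replace = TRUE)
      hap2 <- .BASES[((match(hap1, .BASES) - 1L + shift) %% 4L) + 1L]
      markers[[ch]] <- data.frame(pos = pos, hap1 = hap1, hap2 = hap2,
                                  stringsAsFactors = FALSE)

      # centromeric arrays on a jittered regular grid
      n_arr <- floor(L / config$tyba_spacing)
      if (n_arr >= 1L) {
        centers <- config$tyba_spacing * (seq_len(n_arr) - 0.5) +
          stats::runif(n_arr, -0.1, 0.1) * config$tyba_spacing
        sizes <- stats::rgamma(n_arr, shape = 16, rate = 16 / config$tyba_size)
        a_start <- pmax(0, round(centers - sizes / 2))
        a_end <- pmin(L, a_start + round(sizes))
        tyba[[ch]] <- data.frame(chrom = ch, start = a_start, end = a_end,
                                 stringsAsFactors = FALSE)
        mono[[ch]] <- do.call(rbind, lapply(seq_len(n_arr), function(j) {
          .fragment_array(ch, a_start[j], a_end[j])
        }))
        cenh3[[ch]] <- do.call(rbind, lapply(seq_len(n_arr), function(j) {
          w <- a_end[j] - a_start[j]
          if (w > 6e3 && stats::runif(1) < 0.4) {
            # split domain: two peaks separated by a small (<25 kb) gap
            cut <- a_start[j] + round(w * stats::runif(1, 0.3, 0.7))
            gap <- round(stats::runif(1, 500, 4000))
            data.frame(chrom = ch,
                       start = c(a_start[j], min(cut + gap, a_end[j])),
                       end = c(cut, a_end[j]), stringsAsFactors = FALSE)
          } else {
            data.frame(chrom = ch, start = a_start[j], end = a_end[j],
                       stringsAsFactors = FALSE)
          }
        }))
        mono[[ch]] <- mono[[ch]][mono[[ch]]$end <= L & mono[[ch]]$end > mono[[ch]]$start, ]
      } else {
        tyba[[ch]] <- mono[[ch]] <- cenh3[[ch]] <-
          data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
      }

      n_gene <- round(config$genes_per_mb * L / 1e6)
      if (n_gene >= 1L) {
        gs <- sort(sample.int(L, n_gene))
        gw <- pmax(200, round(stats::rgamma(n_gene, 4, 4 / config$gene_size)))
        genes[[ch]] <- data.frame(chrom = ch, start = gs - 1,
                                  end = pmin(L, gs - 1 + gw),
                                  strand = sample(c("+", "-"), n_gene, TRUE),
                                  stringsAsFactors = FALSE)
      } else {
        genes[[ch]] <- data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), strand = character(0))
      }

      n_te <- round(config$tes_per_mb * L / 1e6)
      if (n_te >= 1L) {
        ts <- sort(sample.int(L, n_te))
        tw <- pmax(100, round(stats::rgamma(n_te, 2, 2 / config$te_size)))
        tes[[ch]] <- data.frame(chrom = ch, start = ts - 1,
                                end = pmin(L, ts - 1 + tw),
                                stringsAsFactors = FALSE)
      } else {
        tes[[ch]] <- data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0))
      }
    }
    collapse <- function(l) {
      out <- do.call(rbind, unname(l))
      rownames(out) <- NULL
      out
    }
    structure(list(
      chromosomes = chroms,
      markers = markers,
      features = list(
        tyba_arrays = collapse(tyba),
        tyba_monomers = collapse(mono),
        cenh3_peaks = collapse(cenh3),
        genes = collapse(genes),
        tes = collapse(tes)
      )
    ), class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  n_mark <- sum(vapply(x$markers, nrow, 0L))
  cat(sprintf(
    "<sim_genome> %d chromosomes, %.3g Mb, %d markers, %d centromeric arrays\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6, n_mark,
    nrow(x$features$tyba_arrays)
  ))
  invisible(x)
}

# named vector chrom -> length
.chrom_lengths <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
}
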