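# Haplotype-diagnostic marker selection from a variant table called against
# the phased haplotype-1 reference.

#' Build a phased marker set
#'
#' @param by_chrom Named list of data.frames with columns `pos` (1-based),
#'   `hap1`, `hap2`. Positions must be strictly increasing after
#'   deduplication; duplicated positions are dropped (first kept) with a
#'   warning; `hap1` must differ from `hap2` everywhere.
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(by_chrom) {
  stopifnot(is.list(by_chrom))
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    dup <- duplicated(d$pos)
    if (any(dup)) {
      warning(sum(dup), " duplicated marker positions dropped")
      d <- d[!dup, , drop = FALSE]
    }
    if (any(d$hap1 == d$hap2)) {
      stop("marker with identical haplotype alleles", call. = FALSE)
    }
    rownames(d) <- NULL
    d
  })
  structure(list(by_chrom = by_chrom), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers on %d chromosomes\n",
              sum(vapply(x$by_chrom, nrow, 0L)), length(x$by_chrom)))
  invisible(x)
}

#' Markers of a simulated genome as a `marker_set`
#' @param genome A `sim_genome`.
#' @return A [marker_set()].
#' @export
markers_from_genome <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  marker_set(genome$markers)
}

#' Load a variant table from a VCF file
#'
#' Reads biallelic records with the per-site annotations needed for marker
#' selection: mapping quality (`MQ`), alternative base coverage (`AO`) and
#' allele frequency (`AF`) from the INFO column. Multiallelic sites are
#' skipped by default (`expand_multiallelic = TRUE` expands them to one row
#' per alternate allele, replicating the site annotations). Indels are
#' retained but flagged.
#'
#' @param path Path to a VCF 4.x file.
#' @param expand_multiallelic Expand multiallelic ALT fields instead of
#'   skipping the site.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`, `mq`,
#'   `alt_cov`, `af`, `is_indel`.
#' @export
load_variants <- function(path, expand_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      mq = numeric(0), alt_cov = numeric(0), af = numeric(0),
                      is_indel = logical(0)))
  }
  info <- data.frame(
    mq = vcfR::extract.info(v, "MQ", as.numeric = TRUE),
    alt_cov = vcfR::extract.info(v, "AO", as.numeric = TRUE),
    af = vcfR::extract.info(v, "AF", as.numeric = TRUE)
  )
  df <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                   ref = fix$REF, alt = fix$ALT, info,
                   stringsAsFactors = FALSE)
  multi <- grepl(",", df$alt, fixed = TRUE)
  if (any(multi)) {
    if (expand_multiallelic) {
      alts <- strsplit(df$alt[multi], ",", fixed = TRUE)
      rep_rows <- df[rep(which(multi), lengths(alts)), , drop = FALSE]
      rep_rows$alt <- unlist(alts)
      df <- rbind(df[!multi, , drop = FALSE], rep_rows)
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
    } else {
      df <- df[!multi, , drop = FALSE]
    }
  }
  df$is_indel <- nchar(df$ref) != 1L | nchar(df$alt) != 1L
  rownames(df) <- NULL
  df
}

#' Select haplotype-diagnostic SNP markers
#'
#' Applies the marker filters used for phased-reference genotyping: SNPs
#' only (no indels), mapping quality strictly greater than `min_mq`, and
#' inclusive bounds on alternative base coverage and allele frequency.
#' With the defaults, the retained set is
#' `{SNP, MQ > 50, 5 <= alt_cov <= 30, 0.4 <= AF <= 0.6}`.
#'
#' @param variants Data.frame from [load_variants()].
#' @param min_mq Strict lower bound on mapping quality.
#' @param cov Length-2 inclusive coverage interval.
#' @param af Length-2 inclusive allele-frequency interval.
#' @return A [marker_set()] with `hap1 = ref`, `hap2 = alt`.
#' @export
select_markers <- function(variants, min_mq = 50, cov = c(5, 30),
                           af = c(0.4, 0.6)) {
  stopifnot(length(cov) == 2L, length(af) == 2L)
  keep <- !variants$is_indel &
    !is.na(variants$mq) & variants$mq > min_mq &
    !is.na(variants$alt_cov) &
    variants$alt_cov >= cov[1] & variants$alt_cov <= cov[2] &
    !is.na(variants$af) & variants$af >= af[1] & variants$af <= af[2]
  kept <- variants[keep, , drop = FALSE]
  by_chrom <- lapply(split(kept, kept$chrom), function(d) {
    data.frame(pos = d$pos, hap1 = d$ref, hap2 = d$alt,
               stringsAsFactors = FALSE)
  })
  marker_set(by_chrom)
}

#' Marker count and spacing summary
#'
#' Mean spacing is defined as total chromosome length divided by total
#' marker count (and likewise per chromosome), so 1,000 markers on a
#' 449,000 bp genome give a spacing of 449 bp.
#'
#' @param markers A [marker_set()].
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return List with `n_markers`, `mean_spacing_bp` and a per-chromosome
#'   data.frame (`chrom`, `n`, `length`, `spacing_bp`, `density_per_bp`).
#' @export
marker_spacing_stats <- function(markers, chrom_lengths) {
  stopifnot(inherits(markers, "marker_set"))
  chroms <- names(markers$by_chrom)
  n <- vapply(markers$by_chrom, nrow, 0L)
  if (sum(n) == 0L) stop("no markers genome-wide", call. = FALSE)
  if (!all(chroms %in% names(chrom_lengths))) {
    stop("chrom_lengths missing entries for some marker chromosomes",
         call. = FALSE)
  }
  L <- as.numeric(chrom_lengths[chroms])
  per <- data.frame(chrom = chroms, n = as.integer(n), length = L,
                    spacing_bp = L / pmax(n, 1L), density_per_bp = n / L,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(n_markers = sum(n),
       mean_spacing_bp = sum(L) / sum(n),
       per_chromosome = per)
}

#' Write markers as a minimal VCF
#'
#' Emits a VCF 4.2 file with one biallelic SNP record per marker
#' (`REF = hap1`, `ALT = hap2`) and `MQ`, `AO`, `AF` INFO annotations, the
#' fields [load_variants()] consumes. Used to round-trip synthetic marker
#' sets through the VCF interface.
#'
#' @param genome A `sim_genome` (or a [marker_set()]).
#' @param path Output path.
#' @param mq,alt_cov,af INFO values, recycled across records.
#' @return `path`, invisibly.
#' @export
write_marker_vcf <- function(genome, path, mq = 60, alt_cov = 15, af = 0.5) {
  by_chrom <- if (inherits(genome, "sim_genome")) genome$markers
              else genome$by_chrom
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele coverage\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- unlist(lapply(names(by_chrom), function(ch) {
    d <- by_chrom[[ch]]
    if (!nrow(d)) return(character(0))
    n <- nrow(d)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMQ=%g;AO=%d;AF=%g",
            ch, as.integer(d$pos), d$hap1, d$hap2,
            rep_len(mq, n), as.integer(rep_len(alt_cov, n)),
            rep_len(af, n))
  }))
  writeLines(c(header, body), path)
  invisible(path)
}
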