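# Readers and writers for the package's plain-text interchange formats.
# Convention: all interval files are BED (0-based half-open); marker-level
# tables are 1-based to match VCF.

#' Write an interval table as BED
#'
#' @param df Interval table; `chrom`, `start`, `end` first, then any of
#'   `name`, `score`, `strand` if present.
#' @param path Output path.
#' @param name_col Optional column to emit as the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  cols <- data.frame(chrom = df$chrom, start = format(df$start, scientific = FALSE, trim = TRUE),
                     end = format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name_col)) cols$name <- df[[name_col]]
  else if ("name" %in% names(df)) cols$name <- df$name
  if ("strand" %in% names(df)) {
    if (is.null(cols$name)) cols$name <- "."
    cols$score <- "."
    cols$strand <- df$strand
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path Path to a BED3+ file.
#' @return Data.frame `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write/read long-format gamete observations
#'
#' Tab-separated with header: `cell_id`, `chrom`, `pos` (1-based),
#' `hap1_reads`, `hap2_reads`.
#'
#' @param observations Observation table.
#' @param path File path.
#' @return `path` (writer) or the observation data.frame (reader).
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(cell_id = "character",
                                   chrom = "character"))
}

#' Write/read a marker table
#'
#' Tab-separated with header: `chrom`, `pos` (1-based), `hap1`, `hap2`.
#'
#' @param markers A [marker_set()].
#' @param path File path.
#' @return `path` (writer) or a `marker_set` (reader).
#' @export
write_marker_table <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  df <- do.call(rbind, lapply(names(markers$by_chrom), function(ch) {
    cbind(chrom = ch, markers$by_chrom[[ch]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  marker_set(lapply(split(df, df$chrom), function(d) {
    data.frame(pos = d$pos, hap1 = d$hap1, hap2 = d$hap2,
               stringsAsFactors = FALSE)
  }))
}
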