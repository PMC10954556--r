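# End-to-end driver: QC -> crossover calling -> landscape and maps ->
# interference -> feature association, with artifact writing and a run
# manifest.

#' Pipeline configuration
#'
#' Defaults are the thresholds of the emulated single-gamete study:
#' cells need more than 5,000 reads and at least 400 markers; cells with a
#' genotype switch rate above 0.07 are doublets; genotype blocks qualify
#' with 5 markers within 1 Mb; recombination rates use 1 Mb windows at
#' 100 kb steps; genetic maps use 500 kb marker thinning; feature
#' association uses 5,000 permutation rounds; centromeric annotations merge
#' with a 25 kb radius. Every parameter is validated at construction.
#'
#' @param min_reads,min_markers Cell QC thresholds.
#' @param switch_threshold Doublet switch-rate cut.
#' @param min_align_rate,ambiguity_delta Species-assignment thresholds
#'   (percent).
#' @param co [co_params()] for the crossover caller.
#' @param window,step Recombination-rate window geometry, bp.
#' @param thin_window Marker-thinning window, bp.
#' @param coc_k Intervals per chromosome for coincidence curves.
#' @param coc_rounds Resampling rounds for coincidence curves.
#' @param perm_rounds Permutation rounds for feature association.
#' @param seed Integer seed used for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 5000, min_markers = 400,
                            switch_threshold = 0.07,
                            min_align_rate = 25, ambiguity_delta = 10,
                            co = co_params(),
                            window = 1e6, step = 1e5,
                            thin_window = 5e5,
                            coc_k = 15L, coc_rounds = 100L,
                            perm_rounds = 5000L, seed = 1L) {
  .check_scalar(min_reads, "min_reads", lower = 0)
  .check_scalar(min_markers, "min_markers", lower = 0)
  .check_scalar(switch_threshold, "switch_threshold", lower = 0, upper = 1)
  .check_scalar(min_align_rate, "min_align_rate", lower = 0, upper = 100)
  .check_scalar(window, "window", lower = 1)
  .check_scalar(step, "step", lower = 1)
  .check_scalar(thin_window, "thin_window", lower = 1)
  .check_scalar(coc_k, "coc_k", lower = 2)
  .check_scalar(perm_rounds, "perm_rounds", lower = 100)
  stopifnot(inherits(co, "co_params"))
  structure(list(min_reads = min_reads, min_markers = min_markers,
                 switch_threshold = switch_threshold,
                 min_align_rate = min_align_rate,
                 ambiguity_delta = ambiguity_delta, co = co,
                 window = window, step = step, thin_window = thin_window,
                 coc_k = as.integer(coc_k),
                 coc_rounds = as.integer(coc_rounds),
                 perm_rounds = as.integer(perm_rounds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML mapping of parameter overrides and merges it into the
#' defaults of [pipeline_config()]. Keys under `co:` override the
#' crossover-caller parameters.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  co_args <- y$co %||% list()
  y$co <- NULL
  do.call(pipeline_config, c(y, list(co = do.call(co_params, co_args))))
}

#' Run the full single-gamete crossover pipeline
#'
#' Chains cell QC (read/marker filters and switch-rate doublet removal),
#' crossover calling, the windowed recombination landscape, marker-thinned
#' Marey maps, interference statistics (Poisson goodness of fit, dispersion
#' test, per-chromosome coincidence curves) and, when feature tracks are
#' supplied, the permutation-based overlap Z-scores. All stochastic stages
#' derive their seeds from `config$seed`, so a rerun with the same inputs
#' and configuration reproduces every artifact byte for byte.
#'
#' @param observations Long-format observation table.
#' @param genome A `sim_genome`, or a list with `chromosomes` (data.frame
#'   `name`, `length`), optional `markers`, optional `features`.
#' @param out_dir Optional directory; when given, artifacts (QC report,
#'   crossover BED, rate bedGraph, genetic map, statistics tables and a
#'   JSON manifest) are written there.
#' @param config A [pipeline_config()].
#' @return List with elements `qc`, `doublets`, `cos`, `track`, `map`,
#'   `counts`, `gof`, `dispersion`, `coc`, `association` (NULL without
#'   features), `n_cells`.
#' @export
run_pipeline <- function(observations, genome, out_dir = NULL,
                         config = pipeline_config()) {
  chrom_info <- genome$chromosomes
  lens <- stats::setNames(chrom_info$length, chrom_info$name)

  qc <- filter_cells(observations, config$min_reads, config$min_markers)
  obs_kept <- observations[observations$cell_id %in% qc$kept, , drop = FALSE]
  if (nrow(obs_kept) == 0L) {
    stop("pipeline stage 'qc': no cells pass the read/marker filters",
         call. = FALSE)
  }
  sw <- switch_rates(obs_kept, config$switch_threshold)
  singletons <- sw$cell_id[!sw$doublet]
  obs_kept <- obs_kept[obs_kept$cell_id %in% singletons, , drop = FALSE]
  if (nrow(obs_kept) == 0L) {
    stop("pipeline stage 'doublets': every cell flagged as doublet",
         call. = FALSE)
  }

  called <- call_crossovers_cohort(obs_kept, config$co)
  n_cells <- length(unique(obs_kept$cell_id))

  conf <- chrom_info
  # confident bounds: first to last observed marker per chromosome
  conf$conf_start <- vapply(conf$name, function(ch) {
    p <- obs_kept$pos[obs_kept$chrom == ch]
    if (length(p)) min(p) - 1 else 0
  }, 0)
  conf$conf_end <- vapply(conf$name, function(ch) {
    p <- obs_kept$pos[obs_kept$chrom == ch]
    if (length(p)) max(p) else conf$length[match(ch, conf$name)]
  }, 0)
  track <- co_rate_track(called$cos, n_cells, conf,
                         window = config$window, step = config$step)

  eval_pos <- lapply(stats::setNames(conf$name, conf$name), function(ch) {
    p <- sort(unique(obs_kept$pos[obs_kept$chrom == ch]))
    if (length(p)) thin_markers(p, config$thin_window) else numeric(0)
  })
  map <- marey_map(called$cos, n_cells, eval_pos, lens)

  counts <- co_count_distribution(called$cos, unique(obs_kept$cell_id),
                                  conf$name)
  gof <- tryCatch(poisson_gof(counts$per_gamete$n_co),
                  error = function(e) NULL)
  disp <- tryCatch(dispersion_test(counts$per_gamete$n_co),
                   error = function(e) NULL)
  coc <- lapply(stats::setNames(conf$name, conf$name), function(ch) {
    d <- called$cos[called$cos$chrom == ch, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    coc_curve(d, unique(obs_kept$cell_id), lens[[ch]], k = config$coc_k,
              rounds = config$coc_rounds, seed = config$seed)
  })

  association <- NULL
  if (!is.null(genome$features) && nrow(called$cos) > 0L) {
    association <- z_scores(called$cos, genome$features, lens,
                            n_rounds = config$perm_rounds,
                            seed = config$seed)
  }

  res <- list(qc = qc$report, doublets = sw, cos = called$cos,
              track = track, map = map, counts = counts, gof = gof,
              dispersion = disp, coc = coc, association = association,
              n_cells = n_cells)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sw, file.path(out_dir, "switch_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(called$cos, file.path(out_dir, "crossovers.bed"),
              name_col = "cell_id")
    utils::write.table(track, file.path(out_dir, "co_rate.bedgraph"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    map_df <- do.call(rbind, lapply(names(map$map), function(ch) {
      cbind(chrom = ch, map$map[[ch]])
    }))
    utils::write.table(map_df, file.path(out_dir, "genetic_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(association)) {
      utils::write.table(association, file.path(out_dir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
      package = "holocross",
      version = as.character(utils::packageVersion("holocross")),
      seed = config$seed,
      n_cells_in = length(unique(observations$cell_id)),
      n_cells_used = n_cells,
      n_crossovers = nrow(called$cos),
      total_map_cM = map$total_cM,
      parameters = unclass(config)[setdiff(names(unclass(config)), "co")],
      co_parameters = unclass(config$co)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
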