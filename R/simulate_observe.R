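# Sparse observation of gametes: which markers a cell reports, with how many
# reads, and with what haplotype error; doublet construction; selfed
# offspring with interval-resolution crossovers.

#' Observation model for sparse single-cell genotyping
#'
#' Emulates the sparsity of droplet scRNA-seq on transcript-poor pollen
#' nuclei: each cell reports a log-normally distributed number of markers
#' (default median 380, so cohorts straddle a 400-marker QC threshold as in
#' the emulated study), usually with a single read per marker, and each read
#' reports the wrong haplotype with probability `error_rate`.
#'
#' @param markers_per_cell Either `list(median =, sdlog =)` for a log-normal
#'   marker count per cell, or `list(capture_prob = p)` to observe every
#'   marker independently with probability `p` (use `p = 1` for exhaustive,
#'   noise-free genotyping in tests).
#' @param reads_per_marker A single integer (constant read count, default 1)
#'   or `list(lambda =)` for `max(1, rpois(lambda))` reads.
#' @param error_rate Probability in `[0, 0.5)` that a read reports the wrong
#'   haplotype.
#' @param doublet_fraction Fraction in `[0, 1)` of emitted cells that are
#'   two gametes merged under one barcode (used by
#'   [simulate_gamete_cohort()]).
#' @return A list of class `observation_model`.
#' @export
observation_model <- function(markers_per_cell = list(median = 380, sdlog = 0.8),
                              reads_per_marker = 1L,
                              error_rate = 0.01,
                              doublet_fraction = 0.05) {
  .check_scalar(error_rate, "error_rate", lower = 0, upper = 0.5,
                strict_upper = TRUE)
  .check_scalar(doublet_fraction, "doublet_fraction", lower = 0, upper = 1,
                strict_upper = TRUE)
  if (!is.list(markers_per_cell)) {
    stop("markers_per_cell must be a list spec", call. = FALSE)
  }
  structure(list(
    markers_per_cell = markers_per_cell,
    reads_per_marker = reads_per_marker,
    error_rate = error_rate,
    doublet_fraction = doublet_fraction
  ), class = "observation_model")
}

# haplotype truly inherited at 1-based positions `pos` on one chromosome
.hap_at <- function(pos, co_pos, start_hap) {
  k <- findInterval(pos, co_pos)
  ifelse(k %% 2L == 0L, start_hap, .other_hap(start_hap))
}

#' Observe one gamete through the sparse single-cell model
#'
#' Draws the observed marker subset, read depths and haplotype-labelled read
#' counts for a single gamete. Observed markers are always a subset of the
#' reference markers; every observed marker carries at least one read.
#'
#' @param truth A `gamete_truth_set`.
#' @param i Index of the gamete to observe.
#' @param genome The `sim_genome` the gamete was simulated on.
#' @param obs An [observation_model()].
#' @param seed Integer seed.
#' @param cell_id Barcode to assign (defaults to the truth's cell id).
#' @return Data.frame with columns `cell_id`, `chrom`, `pos` (1-based),
#'   `hap1_reads`, `hap2_reads`, sorted by chromosome and position.
#' @export
observe_gamete <- function(truth, i, genome, obs = observation_model(),
                           seed = 1L, cell_id = NULL) {
  stopifnot(inherits(truth, "gamete_truth_set"), inherits(genome, "sim_genome"),
            inherits(obs, "observation_model"))
  cell_id <- cell_id %||% truth$cell_ids[i]
  g <- truth$gametes[[i]]
  with_seed(seed, {
    n_per_chrom <- vapply(genome$markers, nrow, 0L)
    total <- sum(n_per_chrom)
    mpc <- obs$markers_per_cell
    if (!is.null(mpc$capture_prob)) {
      keep <- stats::runif(total) < mpc$capture_prob
      idx <- which(keep)
    } else {
      n_obs <- round(stats::rlnorm(1, meanlog = log(mpc$median),
                                   sdlog = mpc$sdlog %||% 0.8))
      n_obs <- min(max(n_obs, 0L), total)
      idx <- sort(sample.int(total, n_obs))
    }
    if (!length(idx)) {
      return(data.frame(cell_id = character(0), chrom = character(0),
                        pos = numeric(0), hap1_reads = integer(0),
                        hap2_reads = integer(0)))
    }
    chrom_of <- rep(names(genome$markers), n_per_chrom)[idx]
    all_pos <- unlist(lapply(genome$markers, function(m) m$pos),
                      use.names = FALSE)
    pos <- all_pos[idx]
    true_hap <- character(length(idx))
    for (ch in unique(chrom_of)) {
      sel <- chrom_of == ch
      true_hap[sel] <- .hap_at(pos[sel], g$cos[[ch]], g$start_hap[[ch]])
    }
    n <- length(idx)
    r <- if (is.list(obs$reads_per_marker)) {
      pmax(1L, stats::rpois(n, obs$reads_per_marker$lambda))
    } else {
      rep(as.integer(obs$reads_per_marker), n)
    }
    correct <- stats::rbinom(n, r, 1 - obs$error_rate)
    hap1 <- ifelse(true_hap == "H1", correct, r - correct)
    out <- data.frame(cell_id = cell_id, chrom = chrom_of, pos = pos,
                      hap1_reads = as.integer(hap1),
                      hap2_reads = as.integer(r - hap1),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$chrom, out$pos), , drop = FALSE]
  })
}

#' Merge two gamete observations into a doublet
#'
#' The doublet's marker set is the union of both cells' markers; read counts
#' are summed at shared markers. The emitted `cell_id` records both source
#' barcodes.
#'
#' @param a,b Observation data.frames from the same genome (as returned by
#'   [observe_gamete()]).
#' @param cell_id Barcode for the merged cell; default
#'   `"<id_a>+<id_b>"`.
#' @return Observation data.frame.
#' @export
make_doublet <- function(a, b, cell_id = NULL) {
  need <- c("cell_id", "chrom", "pos", "hap1_reads", "hap2_reads")
  if (!all(need %in% names(a)) || !all(need %in% names(b))) {
    stop("inputs are not gamete observations", call. = FALSE)
  }
  cell_id <- cell_id %||% paste0(a$cell_id[1] %||% "a", "+", b$cell_id[1] %||% "b")
  m <- rbind(a[, need], b[, need])
  key <- paste(m$chrom, m$pos)
  h1 <- tapply(m$hap1_reads, key, sum)
  h2 <- tapply(m$hap2_reads, key, sum)
  first <- !duplicated(key)
  out <- data.frame(cell_id = cell_id,
                    chrom = m$chrom[first], pos = m$pos[first],
                    hap1_reads = as.integer(h1[key[first]]),
                    hap2_reads = as.integer(h2[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Simulate a full cohort of observed cells with doublets
#'
#' Simulates `n_cells` emitted cells of which `round(doublet_fraction *
#' n_cells)` are doublets built from two additional independent gametes.
#' Per-cell randomness is derived from `seed` by counter so the cohort is
#' reproducible and individual cells can be re-observed in isolation.
#'
#' @param genome A `sim_genome`.
#' @param model A [meiosis_model()].
#' @param obs An [observation_model()].
#' @param n_cells Number of emitted cells.
#' @param seed Integer seed.
#' @return List with `observations` (long data.frame over all cells),
#'   `truth` (the underlying `gamete_truth_set`), and `labels`
#'   (data.frame `cell_id`, `type` ("singleton"/"doublet"), `gamete_i`,
#'   `gamete_j`).
#' @export
simulate_gamete_cohort <- function(genome, model = meiosis_model(),
                                   obs = observation_model(), n_cells,
                                   seed = 1L) {
  .check_scalar(n_cells, "n_cells", lower = 1)
  n_cells <- as.integer(n_cells)
  n_doub <- round(obs$doublet_fraction * n_cells)
  n_single <- n_cells - n_doub
  n_gam <- n_single + 2L * n_doub
  truth <- simulate_meiosis(genome, model, n_gam, seed = seed)
  obs_list <- vector("list", n_cells)
  labels <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n_cells)),
                       type = rep(c("singleton", "doublet"),
                                  c(n_single, n_doub)),
                       gamete_i = NA_integer_, gamete_j = NA_integer_,
                       stringsAsFactors = FALSE)
  for (k in seq_len(n_single)) {
    labels$gamete_i[k] <- k
    obs_list[[k]] <- observe_gamete(truth, k, genome, obs, seed = seed + k,
                                    cell_id = labels$cell_id[k])
  }
  for (d in seq_len(n_doub)) {
    i <- n_single + 2L * d - 1L
    j <- n_single + 2L * d
    k <- n_single + d
    labels$gamete_i[k] <- i
    labels$gamete_j[k] <- j
    a <- observe_gamete(truth, i, genome, obs, seed = seed + n_gam + i)
    b <- observe_gamete(truth, j, genome, obs, seed = seed + n_gam + j)
    obs_list[[k]] <- make_doublet(a, b, cell_id = labels$cell_id[k])
  }
  observations <- do.call(rbind, obs_list)
  rownames(observations) <- NULL
  list(observations = observations, truth = truth, labels = labels)
}

#' Simulate selfed offspring with interval-resolution crossovers
#'
#' Each offspring inherits the union of the crossovers of two independent
#' gametes; every crossover is reported as an interval whose width is drawn
#' from a log-normal resolution distribution (default median 334 bp with
#' mean ~2 kb, the resolution scale of low-coverage whole-genome-sequenced
#' offspring), centred on the true position and clipped to the chromosome.
#'
#' @param genome A `sim_genome`.
#' @param model A [meiosis_model()].
#' @param n_offspring Number of offspring (>= 1).
#' @param resolution `list(median =, sdlog =)` of the interval-width
#'   distribution in bp.
#' @param seed Integer seed.
#' @return List with `cos` (BED-style data.frame `cell_id`, `chrom`,
#'   `start`, `end`) and `truth` (data.frame of true point positions).
#' @export
simulate_selfed_offspring <- function(genome, model = meiosis_model(),
                                      n_offspring,
                                      resolution = list(median = 334,
                                                        sdlog = 1.892),
                                      seed = 1L) {
  .check_scalar(n_offspring, "n_offspring", lower = 1)
  n_offspring <- as.integer(n_offspring)
  truth <- simulate_meiosis(genome, model, 2L * n_offspring, seed = seed)
  lens <- .chrom_lengths(genome)
  with_seed(seed + 1L, {
    rows <- list(); trows <- list(); r <- 0L
    for (o in seq_len(n_offspring)) {
      g1 <- truth$gametes[[2L * o - 1L]]
      g2 <- truth$gametes[[2L * o]]
      for (ch in names(lens)) {
        p <- sort(c(g1$cos[[ch]], g2$cos[[ch]]))
        if (!length(p)) next
        w <- stats::rlnorm(length(p), meanlog = log(resolution$median),
                           sdlog = resolution$sdlog)
        s <- pmax(0, round(p - w / 2))
        e <- pmin(lens[[ch]], pmax(s + 1, round(p + w / 2)))
        r <- r + 1L
        id <- sprintf("offspring_%03d", o)
        rows[[r]] <- data.frame(cell_id = id, chrom = ch, start = s, end = e,
                                stringsAsFactors = FALSE)
        trows[[r]] <- data.frame(cell_id = id, chrom = ch, pos = p,
                                 stringsAsFactors = FALSE)
      }
    }
    empty <- data.frame(cell_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0))
    cos <- if (r) do.call(rbind, rows) else empty
    tru <- if (r) do.call(rbind, trows) else
      data.frame(cell_id = character(0), chrom = character(0), pos = numeric(0))
    rownames(cos) <- rownames(tru) <- NULL
    list(cos = cos, truth = tru, n_offspring = n_offspring)
  })
}
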