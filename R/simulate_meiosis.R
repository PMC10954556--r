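# Meiosis simulator: crossovers placed by a stationary gamma-renewal process
# on the genetic scale, mapped to physical coordinates through a cumulative
# intensity with optional U-shaped distal bias, then thinned 1/2 from the
# bivalent (chiasma) scale to a single chromatid.

#' Meiosis model parameters
#'
#' @param genetic_length_cM Genetic map length per chromosome in cM
#'   (recycled across chromosomes). The expected crossover count per
#'   chromatid equals `genetic_length_cM / 100`.
#' @param nu Gamma-renewal shape controlling crossover interference.
#'   `nu = 1` gives a Poisson (no-interference) process; larger values give
#'   underdispersed, interference-like placement. The default of 5
#'   corresponds to strong interference, with coincidence suppressed over a
#'   large fraction of the chromosome.
#' @param distal_bias_weight Exponent `w >= 0` of the U-shaped
#'   genetic-to-physical intensity `lambda(s) ~ ((s + 0.02)(1 - s + 0.02))^-w`
#'   on the scaled chromosome `s` in `[0, 1]`. `w = 0` makes the genetic map
#'   uniform in physical position; `w > 0` concentrates crossovers distally.
#' @param p_obligate If `TRUE`, chromatids with zero crossovers are
#'   rejection-sampled until at least one occurs (obligate crossover).
#'   Ignored (with a warning) when the map length is zero.
#' @return A list of class `meiosis_model`.
#' @export
meiosis_model <- function(genetic_length_cM = 60, nu = 5,
                          distal_bias_weight = 0.5, p_obligate = FALSE) {
  if (any(genetic_length_cM < 0)) {
    stop("genetic_length_cM must be >= 0", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu <= 0) {
    stop("`nu` must be a positive number", call. = FALSE)
  }
  .check_scalar(distal_bias_weight, "distal_bias_weight", lower = 0)
  structure(list(
    genetic_length_cM = as.numeric(genetic_length_cM),
    nu = nu,
    distal_bias_weight = distal_bias_weight,
    p_obligate = isTRUE(p_obligate)
  ), class = "meiosis_model")
}

# Inverse CDF (on a grid) of the equilibrium forward-recurrence distribution
# of a Gamma(nu, rate) inter-arrival: F_e(x) = pgamma(x, nu+1, rate) +
# (rate * x / nu) * S(x). Sampling the first event from F_e makes the
# renewal process stationary without burn-in.
.renewal_equilibrium_quantile <- function(nu, rate, n_grid = 4096L) {
  xmax <- stats::qgamma(1 - 1e-12, shape = nu, rate = rate) + 2 * nu / rate
  x <- seq(0, xmax, length.out = n_grid)
  fe <- stats::pgamma(x, nu + 1, rate) +
    (rate * x / nu) * stats::pgamma(x, nu, rate, lower.tail = FALSE)
  fe[n_grid] <- 1
  stats::approxfun(fe, x, rule = 2, ties = "ordered")
}

# Simulate chiasma positions (genetic scale, Morgans) for n bivalents over a
# map of g Morgans: stationary renewal with Gamma(nu, 2 nu) gaps, i.e. rate
# 2 chiasmata per Morgan. Returns a list of increasing position vectors.
.sim_chiasmata <- function(n, g, nu, qe) {
  if (g <= 0 || n == 0L) return(rep(list(numeric(0)), n))
  ids_acc <- list(); pos_acc <- list(); r <- 0L
  cur <- qe(stats::runif(n))
  ids <- seq_len(n)
  repeat {
    keep <- cur < g
    ids <- ids[keep]; cur <- cur[keep]
    if (!length(ids)) break
    r <- r + 1L
    ids_acc[[r]] <- ids
    pos_acc[[r]] <- cur
    cur <- cur + stats::rgamma(length(ids), shape = nu, rate = 2 * nu)
  }
  if (r == 0L) return(rep(list(numeric(0)), n))
  split(unlist(pos_acc), factor(unlist(ids_acc), levels = seq_len(n)))
}

# genetic fraction in [0,1] -> physical fraction in [0,1] under the
# U-shaped intensity; returns a function.
.distal_map <- function(w, n_grid = 2048L) {
  if (w == 0) return(identity)
  s <- seq(0, 1, length.out = n_grid)
  eps <- 0.02
  dens <- ((s + eps) * (1 - s + eps))^(-w)
  cum <- cumsum(dens)
  cum <- (cum - cum[1L]) / (cum[n_grid] - cum[1L])
  stats::approxfun(cum, s, rule = 2, ties = "ordered")
}

#' Simulate meioses and return per-gamete crossover truth
#'
#' For each gamete and chromosome, chiasmata are placed on the genetic scale
#' by a stationary gamma-renewal process (shape `nu`, rate `2 nu` per
#' Morgan, i.e. two chiasmata per Morgan on the bivalent), mapped to
#' physical coordinates, and each chiasma is inherited by the sampled
#' chromatid independently with probability 1/2, so the expected crossover
#' count per chromatid is `genetic_length_cM / 100`. The inherited haplotype
#' alternates at each crossover, starting from a random haplotype.
#'
#' @param genome A [simulate_reference()] genome.
#' @param model A [meiosis_model()].
#' @param n_gametes Number of gametes (>= 1).
#' @param seed Integer seed.
#' @return Object of class `gamete_truth_set`: list with `cell_ids`,
#'   `gametes` (per gamete: `cos`, a named per-chromosome list of crossover
#'   positions in bp, and `start_hap`, the haplotype inherited at the left
#'   chromosome end) and `chromosomes`.
#' @export
simulate_meiosis <- function(genome, model = meiosis_model(), n_gametes,
                             seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"), inherits(model, "meiosis_model"))
  .check_scalar(n_gametes, "n_gametes", lower = 1)
  n_gametes <- as.integer(n_gametes)
  chroms <- genome$chromosomes
  g_cm <- rep_len(model$genetic_length_cM, nrow(chroms))
  with_seed(seed, {
    qe <- .renewal_equilibrium_quantile(model$nu, 2 * model$nu)
    dmap <- .distal_map(model$distal_bias_weight)
    per_chrom <- vector("list", nrow(chroms))
    for (ci in seq_len(nrow(chroms))) {
      g <- g_cm[ci] / 100 # Morgans
      L <- chroms$length[ci]
      draw <- function(n) {
        chi <- .sim_chiasmata(n, g, model$nu, qe)
        lapply(chi, function(p) {
          if (!length(p)) return(numeric(0))
          p <- p[stats::runif(length(p)) < 0.5] # chromatid thinning
          if (!length(p)) return(numeric(0))
          phys <- dmap(p / g) * L
          sort(unique(pmin(pmax(phys, 1), L - 1)))
        })
      }
      cos <- draw(n_gametes)
      if (model$p_obligate && g > 0) {
        repeat {
          empty <- which(vapply(cos, length, 0L) == 0L)
          if (!length(empty)) break
          cos[empty] <- draw(length(empty))
        }
      } else if (model$p_obligate && g <= 0) {
        warning("p_obligate ignored for a chromosome with zero map length")
      }
      per_chrom[[ci]] <- cos
    }
    start_haps <- matrix(
      sample(c("H1", "H2"), n_gametes * nrow(chroms), replace = TRUE),
      nrow = n_gametes
    )
    gametes <- lapply(seq_len(n_gametes), function(i) {
      list(
        cos = stats::setNames(
          lapply(per_chrom, `[[`, i), chroms$name
        ),
        start_hap = stats::setNames(start_haps[i, ], chroms$name)
      )
    })
    structure(list(
      cell_ids = sprintf("gamete_%05d", seq_len(n_gametes)),
      gametes = gametes,
      chromosomes = chroms
    ), class = "gamete_truth_set")
  })
}

#' @export
print.gamete_truth_set <- function(x, ...) {
  cat(sprintf("<gamete_truth_set> %d gametes, %d chromosomes, mean %.2f COs/gamete\n",
              length(x$gametes), nrow(x$chromosomes),
              mean(rowSums(truth_co_counts(x)))))
  invisible(x)
}

#' Per-gamete, per-chromosome true crossover counts
#'
#' @param truth A `gamete_truth_set`.
#' @return Integer matrix, gametes x chromosomes.
#' @export
truth_co_counts <- function(truth) {
  stopifnot(inherits(truth, "gamete_truth_set"))
  n_chrom <- nrow(truth$chromosomes)
  m <- vapply(truth$gametes, function(g) vapply(g$cos, length, 0L),
              integer(n_chrom))
  m <- t(matrix(m, nrow = n_chrom))
  dimnames(m) <- list(truth$cell_ids, truth$chromosomes$name)
  m
}

#' Haplotype segments implied by a gamete's crossovers
#'
#' Segments tile each chromosome exactly (0-based half-open), alternating
#' haplotype at every crossover.
#'
#' @param truth A `gamete_truth_set`.
#' @param i Gamete index.
#' @return BED-style data.frame with columns `chrom`, `start`, `end`, `hap`.
#' @export
truth_segments <- function(truth, i) {
  stopifnot(inherits(truth, "gamete_truth_set"))
  g <- truth$gametes[[i]]
  out <- lapply(seq_len(nrow(truth$chromosomes)), function(ci) {
    ch <- truth$chromosomes$name[ci]
    L <- truth$chromosomes$length[ci]
    b <- c(0, g$cos[[ch]], L)
    n_seg <- length(b) - 1L
    hap0 <- g$start_hap[[ch]]
    haps <- rep(c(hap0, .other_hap(hap0)), length.out = n_seg)
    data.frame(chrom = ch, start = b[-length(b)], end = b[-1L], hap = haps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' True crossover positions as width-1 BED intervals
#'
#' @param truth A `gamete_truth_set`.
#' @return Data.frame `cell_id`, `chrom`, `start`, `end` (0-based half-open,
#'   width 1).
#' @export
truth_co_bed <- function(truth) {
  stopifnot(inherits(truth, "gamete_truth_set"))
  rows <- lapply(seq_along(truth$gametes), function(i) {
    g <- truth$gametes[[i]]
    do.call(rbind, lapply(names(g$cos), function(ch) {
      p <- g$cos[[ch]]
      if (!length(p)) return(NULL)
      data.frame(cell_id = truth$cell_ids[i], chrom = ch,
                 start = floor(p), end = floor(p) + 1,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0))
  }
  rownames(out) <- NULL
  out
}
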