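# Shared small fixtures, built once per test run.

# 5 x 2 Mb genome at study marker density
fix_genome <- simulate_reference(genome_config(), seed = 101)

# single-chromosome genome for chromatid-level statistics
fix_chrom1 <- simulate_reference(
  genome_config(n_chrom = 1, chrom_length = 1e7, marker_spacing = 5000),
  seed = 102
)

fix_lens <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
}

# observe a block of gametes into one long table
observe_cohort <- function(truth, genome, obs, idx, seed0 = 1000) {
  do.call(rbind, lapply(idx, function(i) {
    observe_gamete(truth, i, genome, obs, seed = seed0 + i)
  }))
}

# match called crossover intervals against true point positions
co_accuracy <- function(truth, called, tol = 2e4) {
  n_true <- 0L; matched_true <- 0L; matched_call <- 0L; n_call <- 0L
  for (i in seq_along(truth$gametes)) {
    cid <- truth$cell_ids[i]
    cc <- called[called$cell_id == cid, , drop = FALSE]
    n_call <- n_call + nrow(cc)
    for (ch in names(truth$gametes[[i]]$cos)) {
      tp <- truth$gametes[[i]]$cos[[ch]]
      n_true <- n_true + length(tp)
      d <- cc[cc$chrom == ch, , drop = FALSE]
      if (length(tp) && nrow(d)) {
        matched_true <- matched_true +
          sum(vapply(tp, function(p) {
            any(d$start - tol <= p & d$end + tol >= p)
          }, logical(1)))
        matched_call <- matched_call +
          sum(vapply(seq_len(nrow(d)), function(k) {
            any(tp >= d$start[k] - tol & tp <= d$end[k] + tol)
          }, logical(1)))
      }
    }
  }
  list(recall = matched_true / n_true, precision = matched_call / n_call,
       n_true = n_true, n_call = n_call)
}
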