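test_that("reference geometry tracks the configuration", {
  g <- fix_genome
  for (ch in g$chromosomes$name) {
    L <- g$chromosomes$length[g$chromosomes$name == ch]
    n <- nrow(g$markers[[ch]])
    expect_lt(abs(n - L / 449) / (L / 449), 0.1)
    expect_true(all(diff(g$markers[[ch]]$pos) > 0))
    expect_true(all(g$markers[[ch]]$hap1 != g$markers[[ch]]$hap2))
    arr <- g$features$tyba_arrays
    expect_equal(sum(arr$chrom == ch), 5) # floor(2 Mb / 400 kb)
  }
  expect_lt(abs(mean(g$features$tyba_arrays$end -
                       g$features$tyba_arrays$start) - 2e4) / 2e4, 0.1)
  # all features inside chromosome bounds, tracks sorted
  for (tr in g$features) {
    if (!nrow(tr)) next
    lens <- fix_lens(g)[tr$chrom]
    expect_true(all(tr$start >= 0 & tr$end <= lens))
    expect_false(is.unsorted(order(tr$chrom, tr$start)))
  }

  g0 <- simulate_reference(genome_config(n_chrom = 2, chrom_length = 1e6,
                                         genes_per_mb = 0), seed = 1)
  expect_equal(nrow(g0$features$genes), 0)
  expect_error(genome_config(chrom_length = -5), "positive")
})

test_that("seeds make the generator fully reproducible", {
  expect_identical(simulate_reference(genome_config(), seed = 11),
                   simulate_reference(genome_config(), seed = 11))
  tr1 <- simulate_meiosis(fix_chrom1, meiosis_model(60), 50, seed = 5)
  tr2 <- simulate_meiosis(fix_chrom1, meiosis_model(60), 50, seed = 5)
  expect_identical(tr1, tr2)
  om <- observation_model()
  expect_identical(observe_gamete(tr1, 3, fix_chrom1, om, seed = 9),
                   observe_gamete(tr2, 3, fix_chrom1, om, seed = 9))
})

test_that("meiosis reproduces map length and the Poisson limit", {
  # zero map length: never a crossover
  tr0 <- simulate_meiosis(fix_chrom1, meiosis_model(genetic_length_cM = 0),
                          200, seed = 2)
  expect_true(all(truth_co_counts(tr0) == 0))

  # nu = 1 is a thinned Poisson process: mean L/100, variance/mean ~ 1
  tr <- simulate_meiosis(fix_chrom1,
                         meiosis_model(60, nu = 1, distal_bias_weight = 0),
                         20000, seed = 3)
  cc <- as.vector(truth_co_counts(tr))
  expect_lt(abs(mean(cc) - 0.6), 0.02)
  expect_lt(abs(var(cc) / mean(cc) - 1), 0.05)

  expect_error(meiosis_model(nu = 0), "positive")
})

test_that("count dispersion decreases with the interference shape", {
  ratios <- vapply(c(1, 2, 5, 10), function(nu) {
    tr <- simulate_meiosis(fix_chrom1,
                           meiosis_model(60, nu = nu, distal_bias_weight = 0),
                           20000, seed = 40 + nu)
    cc <- as.vector(truth_co_counts(tr))
    var(cc) / mean(cc)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("distal bias moves crossovers toward chromosome ends", {
  tr <- simulate_meiosis(fix_chrom1,
                         meiosis_model(60, nu = 1, distal_bias_weight = 1),
                         5000, seed = 6)
  p <- unlist(lapply(tr$gametes, function(g) g$cos$chr1))
  L <- fix_chrom1$chromosomes$length[1]
  outer <- mean(p < 0.1 * L | p > 0.9 * L)
  inner <- mean(p > 0.4 * L & p < 0.6 * L)
  expect_gt(outer, inner)
})

test_that("haplotype segments tile chromosomes exactly", {
  tr <- simulate_meiosis(fix_genome, meiosis_model(60), 30, seed = 7)
  for (i in seq_len(30)) {
    seg <- truth_segments(tr, i)
    for (ch in fix_genome$chromosomes$name) {
      s <- seg[seg$chrom == ch, ]
      L <- fix_lens(fix_genome)[[ch]]
      expect_equal(s$start[1], 0)
      expect_equal(s$end[nrow(s)], L)
      if (nrow(s) > 1) {
        expect_equal(s$start[-1], s$end[-nrow(s)])
        expect_true(all(s$hap[-1] != s$hap[-nrow(s)]))
      }
      expect_equal(nrow(s) - 1L, length(tr$gametes[[i]]$cos[[ch]]))
    }
  }
})

test_that("observation model hits its error rate and marker subset", {
  tr <- simulate_meiosis(fix_genome, meiosis_model(60), 2, seed = 8)

  # exhaustive noiseless capture reports every marker on the true haplotype
  om0 <- observation_model(markers_per_cell = list(capture_prob = 1),
                           error_rate = 0)
  ob <- observe_gamete(tr, 1, fix_genome, om0, seed = 1)
  expect_equal(nrow(ob), sum(vapply(fix_genome$markers, nrow, 0L)))
  seg <- truth_segments(tr, 1)
  for (ch in unique(ob$chrom)) {
    d <- ob[ob$chrom == ch, ]
    s <- seg[seg$chrom == ch, ]
    true_hap <- s$hap[findInterval(d$pos - 1, s$start)]
    expect_true(all(ifelse(true_hap == "H1", d$hap1_reads, d$hap2_reads) == 1))
  }

  # error rate: discordant single-read markers at ~epsilon
  om5 <- observation_model(markers_per_cell = list(capture_prob = 0.5),
                           error_rate = 0.05)
  ob5 <- observe_gamete(tr, 2, fix_genome, om5, seed = 2)
  seg2 <- truth_segments(tr, 2)
  disc <- 0L
  for (ch in unique(ob5$chrom)) {
    d <- ob5[ob5$chrom == ch, ]
    s <- seg2[seg2$chrom == ch, ]
    true_hap <- s$hap[findInterval(d$pos - 1, s$start)]
    obs_hap <- ifelse(d$hap1_reads > d$hap2_reads, "H1", "H2")
    disc <- disc + sum(obs_hap != true_hap)
  }
  expect_lt(abs(disc / nrow(ob5) - 0.05), 0.01)

  # observed markers are a subset of reference markers
  expect_true(all(ob5$pos %in% unlist(lapply(fix_genome$markers, `[[`, "pos"))))
  expect_error(observation_model(error_rate = 0.7), "outside")
})

test_that("doublets union markers, sum counts and raise switch rates", {
  tr <- simulate_meiosis(fix_genome, meiosis_model(60), 40, seed = 9)
  om <- observation_model(markers_per_cell = list(median = 800, sdlog = 0.3),
                          error_rate = 0.01)
  a <- observe_gamete(tr, 1, fix_genome, om, seed = 1)
  d_self <- make_doublet(a, a)
  expect_equal(nrow(d_self), nrow(a))
  expect_equal(d_self$hap1_reads, 2L * a$hap1_reads)
  expect_equal(d_self$hap2_reads, 2L * a$hap2_reads)
  expect_match(d_self$cell_id[1], "\\+")

  worse <- vapply(1:20, function(k) {
    x <- observe_gamete(tr, 2 * k - 1, fix_genome, om, seed = 100 + k)
    y <- observe_gamete(tr, 2 * k, fix_genome, om, seed = 200 + k)
    dr <- switch_rate(make_doublet(x, y))$rate
    dr > switch_rate(x)$rate && dr > switch_rate(y)$rate
  }, logical(1))
  expect_true(all(worse))

  # opposite-haplotype merge: both haplotype counts present per marker
  x <- data.frame(cell_id = "x", chrom = "chr1", pos = 1:100 * 10,
                  hap1_reads = 1L, hap2_reads = 0L)
  y <- data.frame(cell_id = "y", chrom = "chr1", pos = 1:100 * 10,
                  hap1_reads = 0L, hap2_reads = 1L)
  d <- make_doublet(x, y)
  expect_true(all(d$hap1_reads == 1 & d$hap2_reads == 1))
})

test_that("selfed offspring carry two gametes' crossovers at interval resolution", {
  off0 <- simulate_selfed_offspring(fix_genome, meiosis_model(0), 10, seed = 3)
  expect_equal(nrow(off0$cos), 0)

  off <- simulate_selfed_offspring(fix_genome,
                                   meiosis_model(60, distal_bias_weight = 0),
                                   300, seed = 4)
  per <- table(factor(off$cos$cell_id,
                      levels = sprintf("offspring_%03d", 1:300)))
  expect_lt(abs(mean(per) - 6), 0.4) # two gametes x 3 crossovers
  w <- off$cos$end - off$cos$start
  expect_lt(abs(stats::median(w) - 334) / 334, 0.15)
  expect_true(all(off$cos$start >= 0))
  expect_true(all(off$cos$end <= fix_lens(fix_genome)[off$cos$chrom]))
})
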