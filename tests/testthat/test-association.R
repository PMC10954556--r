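test_that("overlap counting honours the half-open convention and the oracle", {
  a <- bed("chr1", c(100, 500), c(200, 600))
  b <- bed("chr1", c(300, 700), c(400, 800))
  expect_equal(overlap_count(a, b), 0)
  # 1 bp overlap under half-open coordinates
  expect_equal(overlap_count(bed("chr1", 100, 200), bed("chr1", 199, 300)), 1)
  # abutting half-open intervals do not overlap
  expect_equal(overlap_count(bed("chr1", 100, 200), bed("chr1", 200, 300)), 0)

  set.seed(71)
  for (k in 1:10) {
    q <- random_bed(80); s <- random_bed(60)
    expect_equal(overlap_count(q, s), bf_overlap_count(q, s))
  }
})

test_that("pseudo-crossover placement preserves counts, widths and uniformity", {
  lens <- c(chr1 = 9e7, chr2 = 8e7)
  counts <- c(chr1 = 7L, chr2 = 5L)
  pool <- c(1000, 2000, 40000)
  ps <- permute_pseudo_cos(counts, pool, lens, n_rounds = 200, seed = 3)
  per_round <- table(ps$round, ps$chrom)
  expect_true(all(per_round[, "chr1"] == 7))
  expect_true(all(per_round[, "chr2"] == 5))
  expect_true(all((ps$end - ps$start) %in% pool))
  expect_true(all(ps$start >= 0 & ps$end <= lens[ps$chrom]))

  # unit-width pool: all widths 1, starts uniform over the chromosome
  u <- permute_pseudo_cos(c(chr1 = 10L), 1, c(chr1 = 1e6),
                          n_rounds = 5000, seed = 4)
  expect_true(all(u$end - u$start == 1))
  expect_gt(suppressWarnings(
    ks.test(u$start / (1e6 - 1), "punif")$p.value), 0.01)

  expect_error(permute_pseudo_cos(c(chr1 = 2L), 5e6, c(chr1 = 1e6)),
               "exceeds")
})

test_that("Z-scores detect engineered enrichment and depletion", {
  set.seed(72)
  lens <- c(chr1 = 1e7)
  gs <- sort(sample.int(1e7 - 3e3, 200))
  genes <- bed("chr1", gs, gs + 3e3)
  # a disjoint decoy track occupying different space
  dec_s <- sort(sample(setdiff(seq(0, 1e7 - 2e4, by = 2e4), gs), 100))
  decoys <- bed("chr1", dec_s, dec_s + 500)
  # crossovers forced into genes
  idx <- sample(200, 120)
  cos <- bed("chr1", gs[idx] + 100, gs[idx] + 400)
  zz <- suppressWarnings(
    z_scores(cos, list(genes = genes, decoy = decoys), lens,
             n_rounds = 500, seed = 5)
  )
  expect_gt(zz$z[zz$feature == "genes"], 3)
  expect_lt(zz$z[zz$feature == "decoy"], 0)
  expect_equal(dim(attr(zz, "null_draws")), c(500, 2))
})

test_that("relative distances to flanking units are exact and bounded", {
  units <- bed("chr1", c(1000, 5000, 9000), c(2000, 6000, 10000))
  mk_co <- function(p) bed("chr1", p, p) # degenerate: midpoint = p
  expect_equal(relative_distance_profile(mk_co(4000), units)$r, 2000 / 3000)
  expect_equal(relative_distance_profile(mk_co(3500), units)$r, 0.5)
  expect_equal(relative_distance_profile(mk_co(2000), units)$r, 0)
  # inside a unit, before the first and after the last: excluded
  p_in <- relative_distance_profile(mk_co(1500), units)
  expect_length(p_in$r, 0); expect_equal(p_in$n_inside, 1)
  p_out <- relative_distance_profile(rbind(mk_co(500), mk_co(9999999)), units)
  expect_equal(p_out$n_outside, 2)

  set.seed(73)
  big <- merge_cenh3(fix_genome$features$cenh3_peaks)
  s <- runif(500, 0, 2e6)
  r <- relative_distance_profile(bed(sample(fix_genome$chromosomes$name, 500,
                                            replace = TRUE),
                                     s, s + 1), big)$r
  expect_true(all(r >= 0 & r <= 1))
})

test_that("uniform placement between units yields a flat relative profile", {
  set.seed(74)
  units <- bed("chr1", seq(0, 9.9e6, by = 1e5), seq(0, 9.9e6, by = 1e5) + 2e4)
  # sample uniformly inside the inter-unit gaps
  gap_starts <- units$end[-nrow(units)]
  gap_ends <- units$start[-1]
  gi <- sample(length(gap_starts), 5000, replace = TRUE)
  p <- gap_starts[gi] + runif(5000) * (gap_ends[gi] - gap_starts[gi])
  prof <- relative_distance_profile(bed("chr1", p, p), units, n_bins = 10)
  expect_gt(chisq.test(prof$bins$count)$p.value, 0.01)
})

test_that("metagene profiles are strand-aware and conserve mass", {
  genes <- bed("chr1", c(1e4, 5e4), c(2e4, 6e4), strand = c("+", "-"))
  none <- metagene_profile(data.frame(chrom = character(0), pos = numeric(0)),
                           genes)
  expect_true(all(none$count == 0))

  # points at feature midpoints fall in the central body bin
  mids <- data.frame(chrom = "chr1", pos = c(1.5e4, 5.5e4))
  prof <- metagene_profile(mids, genes, n_bins = 50, flank = 2500)
  expect_equal(sum(prof$count), 2)
  expect_equal(prof$count[prof$zone == "body"][26], 2)
  expect_equal(sum(prof$count[prof$zone == "body"]), 2)

  # promoter points: upstream of the TSS on each strand maps to the
  # upstream flank after orientation
  prom <- data.frame(chrom = "chr1", pos = c(1e4 - 1000, 6e4 + 1000))
  pp <- metagene_profile(prom, genes, n_bins = 50, flank = 2500)
  expect_equal(sum(pp$count[pp$zone == "upstream"]), 2)
  expect_equal(sum(pp$count[pp$zone != "upstream"]), 0)

  expect_error(metagene_profile(mids, bed("chr1", 10, 10)), "degenerate")
})

test_that("window correlations recover engineered and null relationships", {
  set.seed(75)
  n <- 500
  a <- rnorm(n)
  mat <- cbind(a = a, minus_a = -a, noise1 = rnorm(n), noise2 = rnorm(n),
               flat = rep(1, n))
  cc <- window_correlation_matrix(mat)
  expect_equal(cc["a", "a"], 1)
  expect_equal(cc["a", "minus_a"], -1)
  expect_lt(abs(cc["noise1", "noise2"]), 0.15)
  expect_true(all(is.na(cc["flat", ])))
  expect_error(window_correlation_matrix(mat[1:2, ]), "at least 3")

  # matrix construction from tracks
  info <- data.frame(name = "chr1", length = 5e6)
  tr <- list(genes = bed("chr1", 1:40 * 1e5, 1:40 * 1e5 + 1e3))
  m <- feature_window_matrix(tr, info, window = 1e6, step = 5e5)
  expect_equal(ncol(m), 1)
  expect_true(all(m >= 0))
})
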