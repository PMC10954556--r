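test_that("allele-frequency smoothing equals the sliding-mean oracle", {
  # isolated error absorbed: (0,0,1,0,0) -> centre 0.2 -> H1
  saf <- smooth_allele_frequencies(c(0, 0, 1, 0, 0))
  expect_equal(saf[3], 0.2)
  expect_true(all(saf < 0.5))

  expect_equal(smooth_allele_frequencies(rep(0, 10)), rep(0, 10))
  expect_equal(smooth_allele_frequencies(numeric(0)), numeric(0))

  set.seed(41)
  for (k in 1:20) {
    af <- runif(sample(1:50, 1))
    for (w in 0:3) {
      expect_equal(smooth_allele_frequencies(af, w), bf_smooth_af(af, w))
    }
  }
})

test_that("genotype smoothing equals the majority-vote oracle", {
  expect_equal(smooth_genotypes(c("H1", "H1", "H2", "H1", "H1"))[3], "H1")
  all_na <- rep(NA_character_, 6)
  expect_equal(smooth_genotypes(all_na), all_na)

  set.seed(42)
  for (k in 1:20) {
    gt <- sample(c("H1", "H2", NA), sample(1:60, 1), replace = TRUE,
                 prob = c(0.45, 0.45, 0.1))
    for (w in 1:3) {
      expect_equal(smooth_genotypes(gt, w), bf_majority_genotype(gt, w))
    }
  }
})

test_that("block building and qualification equal the run-length oracle", {
  # 5 same-genotype markers spanning 0.8 Mb -> one qualified block
  b <- build_blocks(seq(1, 8e5, length.out = 5), rep("H1", 5))
  expect_equal(nrow(b), 1)
  expect_true(b$qualified)

  # 4 markers: block exists but is unqualified
  b4 <- build_blocks(1:4 * 1000, rep("H2", 4))
  expect_equal(nrow(b4), 1)
  expect_false(b4$qualified)

  # 5 markers spanning > 1 Mb with no dense 5-marker core: unqualified
  b5 <- build_blocks(c(1, 4e5, 8e5, 1.2e6, 1.6e6), rep("H1", 5))
  expect_false(b5$qualified)

  # a long sparse block with one dense 5-marker core qualifies
  b6 <- build_blocks(c(1, 5e5, 1e6, 1.5e6, 2e6, 2.1e6, 2.2e6, 2.3e6, 2.4e6),
                     rep("H1", 9))
  expect_true(b6$qualified)

  set.seed(43)
  for (k in 1:20) {
    n <- sample(5:80, 1)
    pos <- sort(sample.int(3e6, n))
    gt <- sample(c("H1", "H2", NA), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
    got <- build_blocks(pos, gt)
    want <- bf_blocks(pos, gt)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("crossovers are called at genotype conversions between qualified blocks", {
  pos <- c(1:5 * 1e4, 6:10 * 1e4 + 5e5)
  gt <- rep(c("H1", "H2"), each = 5)
  bl <- build_blocks(pos, gt)
  cc <- call_crossovers(bl, "chr1", "cellA")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$start, 5e4)            # last marker of the upstream block
  expect_equal(cc$end, 5e5 + 6e4 - 1)    # up to the first downstream marker

  # single qualified block: no crossovers
  expect_equal(nrow(call_crossovers(build_blocks(1:6 * 1e4, rep("H1", 6)),
                                    "chr1", "c")), 0)

  # unqualified block between two same-genotype qualified blocks: merged,
  # no call; between different genotypes: one call spanning the gap
  pos3 <- c(1:5 * 1e4, 6e5 + 1:3 * 1e4, 2e6 + 1:5 * 1e4)
  gt_same <- c(rep("H1", 5), rep("H2", 3), rep("H1", 5))
  expect_equal(nrow(call_crossovers(build_blocks(pos3, gt_same), "chr1", "c")), 0)
  gt_diff <- c(rep("H1", 5), rep("H1", 3), rep("H2", 5))
  cc3 <- call_crossovers(build_blocks(pos3, gt_diff), "chr1", "c")
  expect_equal(nrow(cc3), 1)
  expect_equal(cc3$start, 6e5 + 3e4) # unqualified markers inside the interval
})

test_that("close double crossovers are dropped unless well supported", {
  # three qualified blocks H1/H2/H1 with crossovers ~0.5 Mb apart
  mkpos <- function(o, n) o + seq_len(n) * 1e3
  pos <- c(mkpos(0, 6), mkpos(5e5, 6), mkpos(1e6, 6))
  gt <- rep(c("H1", "H2", "H1"), each = 6)
  bl <- build_blocks(pos, gt)
  # 6-marker support < 10: the close pair is dropped
  expect_equal(nrow(call_crossovers(bl, "chr1", "c")), 0)
  # with >= 10 markers per block the pair is rescued
  pos2 <- c(mkpos(0, 12), mkpos(5e5, 12), mkpos(1e6, 12))
  bl2 <- build_blocks(pos2, rep(c("H1", "H2", "H1"), each = 12))
  cc2 <- call_crossovers(bl2, "chr1", "c")
  expect_equal(nrow(cc2), 2)
  expect_true(all(cc2$close_double_co))
  # far-apart double crossovers are never flagged
  pos3 <- c(mkpos(0, 6), mkpos(3e6, 6), mkpos(6e6, 6))
  cc3 <- call_crossovers(build_blocks(pos3, rep(c("H1", "H2", "H1"), each = 6)),
                         "chr1", "c")
  expect_equal(nrow(cc3), 2)
  expect_false(any(cc3$close_double_co))
})

test_that("noiseless dense gametes are genotyped exactly", {
  tr <- simulate_meiosis(fix_genome, meiosis_model(60, distal_bias_weight = 0),
                         20, seed = 44)
  om <- observation_model(markers_per_cell = list(capture_prob = 1),
                          error_rate = 0)
  for (i in 1:20) {
    ob <- observe_gamete(tr, i, fix_genome, om, seed = 44 + i)
    res <- genotype_cell(ob, quiet = TRUE)
    # only crossovers with enough flanking markers to qualify a block on
    # both sides are detectable at all
    detectable <- lapply(names(tr$gametes[[i]]$cos), function(ch) {
      p <- ob$pos[ob$chrom == ch]
      cos_ch <- tr$gametes[[i]]$cos[[ch]]
      cos_ch[vapply(cos_ch, function(x) {
        sum(p < x) >= 5 && sum(p > x) >= 5
      }, logical(1))]
    })
    names(detectable) <- names(tr$gametes[[i]]$cos)
    expect_equal(res$n_co, sum(lengths(detectable)))
    # every detectable crossover position falls inside its called interval
    for (ch in names(detectable)) {
      for (p in detectable[[ch]]) {
        d <- res$cos[res$cos$chrom == ch, ]
        expect_true(any(d$start <= p & d$end >= p - 1))
      }
    }
    # emitted intervals are valid and inside the chromosome
    expect_true(all(res$cos$start < res$cos$end))
    expect_true(all(res$cos$end <= fix_lens(fix_genome)[res$cos$chrom]))
  }
})

test_that("calls are invariant under coordinate translation", {
  tr <- simulate_meiosis(fix_chrom1, meiosis_model(120), 5, seed = 45)
  om <- observation_model(markers_per_cell = list(capture_prob = 0.5),
                          error_rate = 0.02)
  ob <- observe_gamete(tr, 1, fix_chrom1, om, seed = 46)
  shift <- 123456
  ob2 <- ob; ob2$pos <- ob2$pos + shift
  r1 <- genotype_cell(ob, quiet = TRUE)$cos
  r2 <- genotype_cell(ob2, quiet = TRUE)$cos
  expect_equal(r2$start, r1$start + shift)
  expect_equal(r2$end, r1$end + shift)
})

test_that("recall does not improve when allele error increases", {
  tr <- simulate_meiosis(fix_genome, meiosis_model(60, distal_bias_weight = 0),
                         100, seed = 47)
  om_at <- function(e) observation_model(
    markers_per_cell = list(capture_prob = 0.25), error_rate = e
  )
  recalls <- vapply(c(0, 0.1), function(e) {
    obs <- observe_cohort(tr, fix_genome, om_at(e), 1:100, seed0 = 5000)
    called <- call_crossovers_cohort(obs)
    co_accuracy(tr, called$cos)$recall
  }, numeric(1))
  expect_gte(recalls[1] + 0.02, recalls[2])
  expect_gt(recalls[1], 0.9)
})

test_that("cells with no markers yield no calls", {
  empty <- data.frame(cell_id = character(0), chrom = character(0),
                      pos = numeric(0), hap1_reads = integer(0),
                      hap2_reads = integer(0))
  res <- genotype_cell(empty, quiet = TRUE)
  expect_equal(res$n_co, 0)
  sparse <- data.frame(cell_id = "s", chrom = "chr1", pos = c(1e3, 2e3),
                       hap1_reads = 1L, hap2_reads = 0L)
  expect_warning(genotype_cell(sparse), "no qualified")
})
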