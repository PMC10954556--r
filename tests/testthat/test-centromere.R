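test_that("repeat-array merging applies its three rules in order", {
  # two 5 kb monomers 20 kb apart merge into one 30 kb array
  m <- bed("chr1", c(0, 25000), c(5000, 30000))
  out <- merge_tyba(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$width, 30000)

  # spurious short monomer dropped before merging
  expect_equal(nrow(merge_tyba(bed("chr1", 0, 400))), 0)
  # merged array below the size floor dropped last
  expect_equal(nrow(merge_tyba(bed("chr1", 0, 1500))), 0)
  # the gap rule is inclusive: exactly 25 kb still merges
  gap25 <- merge_tyba(bed("chr1", c(0, 30000), c(5000, 35000)))
  expect_equal(nrow(gap25), 1)
  # 25,001 bp does not
  gap_over <- merge_tyba(bed("chr1", c(0, 30001), c(5000, 35001)))
  expect_equal(nrow(gap_over), 2)
})

test_that("ChIP-domain merging is strict at the gap and floors at 1 kb", {
  # a gap of exactly 25 kb is NOT merged ("less than")
  p <- bed("chr1", c(0, 27000), c(2000, 30000))
  expect_equal(nrow(merge_cenh3(p)), 2)
  p2 <- bed("chr1", c(0, 26999), c(2000, 30000))
  expect_equal(nrow(merge_cenh3(p2)), 1)
  # 900 bp isolated peak dropped
  expect_equal(nrow(merge_cenh3(bed("chr1", 0, 900))), 0)
})

test_that("merging matches the brute-force oracle and is idempotent", {
  set.seed(81)
  for (k in 1:15) {
    n <- sample(5:60, 1)
    s <- sort(sample.int(5e5, n))
    iv <- bed(sample(c("chr1", "chr2"), n, replace = TRUE), s,
              s + sample.int(3e4, n, replace = TRUE))
    got_t <- merge_tyba(iv)
    want_t <- bf_merge(iv, 500, 25000, 2000, strict = FALSE)
    expect_equal(got_t[, c("chrom", "start", "end")], want_t,
                 ignore_attr = TRUE)
    got_c <- merge_cenh3(iv)
    want_c <- bf_merge(iv, 0, 25000, 1000, strict = TRUE)
    expect_equal(got_c[, c("chrom", "start", "end")], want_c,
                 ignore_attr = TRUE)

    # idempotence and ordering/disjointness invariants
    expect_equal(merge_tyba(got_t)[, c("chrom", "start", "end")],
                 got_t[, c("chrom", "start", "end")])
    expect_equal(merge_cenh3(got_c)[, c("chrom", "start", "end")],
                 got_c[, c("chrom", "start", "end")])
    for (d in list(got_t, got_c)) {
      for (ch in unique(d$chrom)) {
        dd <- d[d$chrom == ch, ]
        if (nrow(dd) > 1) expect_true(all(dd$start[-1] > dd$end[-nrow(dd)]))
        # coverage never exceeds the span of surviving monomers
        expect_lte(sum(dd$end - dd$start), max(dd$end) - min(dd$start))
      }
    }
  }
})

test_that("monomer merging recovers the generating arrays", {
  arrays <- merge_tyba(fix_genome$features$tyba_monomers)
  truth <- fix_genome$features$tyba_arrays
  expect_equal(nrow(arrays), nrow(truth))
  expect_lt(max(abs(arrays$start - truth$start)), 2e4)
})

test_that("syntenic pairing is one-to-one and recovers jittered copies", {
  blocks <- data.frame(chrom = "chr1", h1_start = 0, h1_end = 1e6,
                       h2_start = 0, h2_end = 1.1e6)
  s1 <- seq(5e4, 9.5e5, by = 1e5)
  h1 <- bed("chr1", s1, s1 + 2e4)
  # haplotype 2: same relative positions, scaled 1.1x, small jitter
  set.seed(82)
  s2 <- s1 * 1.1 + runif(length(s1), -2e3, 2e3)
  h2 <- bed("chr1", s2, s2 + 2e4)
  pr <- pair_arrays(merge_tyba(h1), merge_tyba(h2), blocks)
  expect_equal(pr$n_pairs, length(s1))
  expect_true(all(abs(pr$pairs$drel) < 0.01))
  # identical annotations: all relative offsets exactly zero
  pr0 <- pair_arrays(merge_tyba(h1), merge_tyba(h1),
                     data.frame(chrom = "chr1", h1_start = 0, h1_end = 1e6,
                                h2_start = 0, h2_end = 1e6))
  expect_true(all(pr0$pairs$drel == 0))
  # each array used at most once
  expect_false(any(duplicated(pr$pairs$h1_row)))
  expect_false(any(duplicated(pr$pairs$h2_row)))
  expect_error(pair_arrays(h1, h2, NULL), "empty")
})

test_that("the comparison battery is calibrated and detects shifts", {
  set.seed(83)
  blocks <- data.frame(chrom = paste0("chr", 1:5),
                       h1_start = 0, h1_end = 2e6,
                       h2_start = 0, h2_end = 2e6)
  draw_arrays <- function() {
    do.call(rbind, lapply(blocks$chrom, function(ch) {
      s <- sort(runif(rpois(1, 30) + 10, 0, 2e6 - 3e4))
      bed(ch, s, s + rgamma(length(s), 16, 16 / 2e4))
    }))
  }
  # same generative process in both haplotypes: battery mostly silent
  n_sig <- replicate(40, {
    h1 <- draw_arrays(); h2 <- draw_arrays()
    pr <- pair_arrays(h1, h2, blocks)
    st <- compare_array_stats(h1, h2, pr)
    ps <- c(st$f_test$p.value, st$t_test$p.value,
            st$mann_whitney_size$p.value, st$ks_position$p.value)
    sum(ps < 0.01, na.rm = TRUE)
  })
  expect_gte(mean(n_sig == 0), 0.9)

  # doubled sizes: the rank test fires
  h1 <- draw_arrays()
  h2 <- h1; h2$end <- h2$start + 2 * (h1$end - h1$start)
  st2 <- compare_array_stats(h1, h2, pair_arrays(h1, h2, blocks))
  expect_lt(st2$mann_whitney_size$p.value, 0.01)
  # identical samples: KS distance zero
  st3 <- compare_array_stats(h1, h1, pair_arrays(h1, h1, blocks))
  expect_equal(unname(st3$ks_position$statistic), 0)
  # unbiased pairs: regression of offset on position is flat at zero
  set.seed(84)
  hA <- draw_arrays()
  hB <- hA; hB$start <- hB$start + runif(nrow(hB), -5e3, 5e3)
  hB$end <- hB$end + runif(nrow(hB), -5e3, 5e3)
  stR <- compare_array_stats(hA, hB, pair_arrays(hA, hB, blocks))
  expect_lt(abs(stR$regression$slope), 0.02)
  expect_lt(abs(stR$regression$intercept), 0.02)
})
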