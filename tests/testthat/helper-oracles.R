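# Independent brute-force oracles used to cross-check the vectorised
# implementations. These are deliberately naive (quadratic loops, direct
# definitions) and share no code with the package internals.

bf_smooth_af <- function(af, w = 2L) {
  n <- length(af)
  vapply(seq_len(n), function(i) {
    mean(af[max(1, i - w):min(n, i + w)])
  }, numeric(1))
}

bf_majority_genotype <- function(gt, w = 2L) {
  n <- length(gt)
  vapply(seq_len(n), function(i) {
    win <- gt[max(1, i - w):min(n, i + w)]
    n1 <- sum(win == "H1", na.rm = TRUE)
    n2 <- sum(win == "H2", na.rm = TRUE)
    if (n1 > n2) "H1" else if (n2 > n1) "H2" else gt[i]
  }, character(1))
}

bf_blocks <- function(pos, gt, min_markers = 5L, span = 1e6) {
  keep <- !is.na(gt)
  pos <- pos[keep]; gt <- gt[keep]
  if (!length(pos)) return(NULL)
  out <- list(); cur <- 1L
  for (i in seq_along(gt)[-1]) {
    if (gt[i] != gt[cur]) {
      out[[length(out) + 1L]] <- c(cur, i - 1L)
      cur <- i
    }
  }
  out[[length(out) + 1L]] <- c(cur, length(gt))
  do.call(rbind, lapply(out, function(se) {
    p <- pos[se[1]:se[2]]
    qual <- FALSE
    if (length(p) >= min_markers) {
      for (s in 1:(length(p) - min_markers + 1L)) {
        if (p[s + min_markers - 1L] - p[s] <= span) qual <- TRUE
      }
    }
    data.frame(start_pos = p[1], end_pos = p[length(p)], genotype = gt[se[1]],
               n_markers = length(p), qualified = qual,
               stringsAsFactors = FALSE)
  }))
}

bf_overlap_count <- function(cos, features) {
  n <- 0L
  for (i in seq_len(nrow(cos))) {
    hit <- FALSE
    qs <- cos$start[i]; qe <- max(cos$end[i], cos$start[i] + 1)
    for (j in seq_len(nrow(features))) {
      if (cos$chrom[i] != features$chrom[j]) next
      fs <- features$start[j]; fe <- max(features$end[j], features$start[j] + 1)
      if (qs < fe && fs < qe) hit <- TRUE
    }
    if (hit) n <- n + 1L
  }
  n
}

bf_thin <- function(pos, window = 5e5) {
  first <- pos[1]
  sel <- numeric(0)
  b <- 0L
  repeat {
    lo <- first + b * window
    if (lo > pos[length(pos)]) break
    inw <- which(pos >= lo & pos < lo + window)
    if (length(inw)) {
      k <- if (length(inw) %% 2 == 0) length(inw) / 2 else (length(inw) + 1) / 2
      sel <- c(sel, pos[inw[k]])
    }
    b <- b + 1L
  }
  sel
}

# three-step merge oracle; strict controls the gap comparison
bf_merge <- function(iv, min_pre, gap, min_post, strict = FALSE) {
  iv <- iv[iv$end - iv$start >= min_pre, , drop = FALSE]
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- NULL
  for (ch in unique(iv$chrom)) {
    d <- iv[iv$chrom == ch, , drop = FALSE]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      g <- d$start[i] - ce
      merge_it <- if (strict) g < gap else g <= gap
      if (merge_it) ce <- max(ce, d$end[i])
      else {
        out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
        cs <- d$start[i]; ce <- d$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
  }
  out <- out[out$end - out$start >= min_post, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random interval table generator for oracle tests
random_bed <- function(n, chroms = c("chr1", "chr2"), L = 1e6,
                       max_width = 5e4) {
  s <- floor(runif(n, 0, L - max_width))
  bed(sample(chroms, n, replace = TRUE), s, s + ceiling(runif(n, 1, max_width)))
}
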