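test_that("constant profiles give one segment per chromosome", {
  win <- toy_windows(c(40, 30))
  x <- rep(0.1, 70)
  for (seg in list(cbs_segment(x, win, seed = 1), alt_segment(x, win))) {
    expect_equal(nrow(seg), 2)
    expect_equal(seg$n_windows, c(40, 30))
    expect_equal(seg$mean_log2, c(0.1, 0.1))
  }
})

test_that("a clear step is found where exhaustive SSE search puts it", {
  set.seed(5)
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  oracle <- oracle_best_cuts(x, 1)

  seg <- cbs_segment(x, seed = 2)
  expect_equal(nrow(seg), 2)
  expect_equal(segment_cuts(seg), oracle)
  expect_lte(abs(segment_cuts(seg) - 50), 1)

  seg2 <- alt_segment(x)
  expect_equal(segment_cuts(seg2), oracle)
})

test_that("CBS split rate on pure noise is near the nominal alpha", {
  set.seed(99)
  splits <- vapply(1:60, function(i) {
    x <- rnorm(100)
    nrow(cbs_segment(x, alpha = 0.01, seed = i)) > 1
  }, TRUE)
  # binomial upper bound for p = 0.01, n = 60 (undo can only reduce the rate)
  expect_lte(sum(splits), qbinom(0.999, 60, 0.01) + 1)
})

test_that("the penalized segmenter is an exact optimizer", {
  set.seed(8)
  x <- c(rnorm(20, 0, 0.1), rnorm(25, 1.2, 0.1), rnorm(15, 0.4, 0.1))
  pen <- 0.5
  seg <- alt_segment(x, penalty = pen)
  expect_equal(segment_cuts(seg), oracle_penalized_cuts(x, pen))

  # penalty -> infinity: a single segment
  seg1 <- alt_segment(x, penalty = 1e9)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$mean_log2, mean(x))
})

test_that("consensus is the breakpoint union with re-merging", {
  x <- c(rep(0, 50), rep(0.5, 20), rep(1, 30))
  a <- alt_segment(x, penalty = 0.5)  # finds both cuts
  expect_identical(consensus_segments(a, a, x), a)

  # disjoint single cuts {50} and {70} -> union {50, 70}
  mk <- function(v, cuts) {
    bounds <- c(0, cuts, length(v))
    do.call(rbind, lapply(seq_len(length(bounds) - 1), function(k) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      data.frame(chrom = "chr1", start_window = bounds[k],
                 end_window = bounds[k + 1],
                 start = bounds[k], end = bounds[k + 1],
                 n_windows = length(idx),
                 mean_log2 = mean(v[idx]), mean_ratio = mean(2^v[idx]))
    }))
  }
  cons <- consensus_segments(mk(x, 50), mk(x, 70), x, merge_tol = 0)
  expect_equal(segment_cuts(cons), c(50, 70))

  # pieces with equal means collapse back into one
  flat <- rep(0.3, 100)
  cons <- consensus_segments(mk(flat, 50), mk(flat, 70), flat,
                             merge_tol = 0.05)
  expect_equal(nrow(cons), 1)
})

test_that("segment calls follow the +/-0.2 thresholds", {
  seg <- data.frame(mean_log2 = c(0.25, 0, -0.21, 0.2, -0.2))
  out <- classify_segments(seg)
  expect_equal(out$call, c("gain", "balanced", "loss", "balanced", "balanced"))
  expect_error(classify_segments(seg, gain_threshold = -1), "gain_threshold")
})

test_that("segmentation is invariant to profile-wide shifts", {
  set.seed(12)
  x <- c(rnorm(40, 0, 0.1), rnorm(40, 0.8, 0.1))
  s1 <- cbs_segment(x, seed = 3)
  s2 <- cbs_segment(x + 5, seed = 3)
  expect_equal(segment_cuts(s1), segment_cuts(s2))
  expect_equal(s2$mean_log2, s1$mean_log2 + 5)
  expect_equal(segment_cuts(alt_segment(x)), segment_cuts(alt_segment(x + 5)))
})

test_that("masked windows are excised but coverage is conserved", {
  win <- toy_windows(c(60))
  set.seed(4)
  x <- c(rnorm(30, 0, 0.1), rnorm(30, 1, 0.1))
  usable <- rep(TRUE, 60)
  usable[c(10, 29, 30, 31, 50)] <- FALSE
  for (seg in list(cbs_segment(x, win, usable, seed = 5),
                   alt_segment(x, win, usable))) {
    expect_equal(sum(seg$n_windows), sum(usable))
    # segments span gaps in genomic coordinates but never overlap
    expect_true(all(seg$start_window[-1] >= seg$end_window[-nrow(seg)]))
  }
})

test_that("both segmenters match brute force on short two-change series", {
  # segment lengths stay >= 7/8 windows: shorter segments cannot reach the
  # permutation alpha on series this size (combinatorial p-value floor)
  set.seed(77)
  ok <- logical(40)
  for (case in 1:40) {
    k <- sample(1:2, 1)
    min_seg <- if (k == 1) 7 else 8
    n <- if (k == 1) sample(16:30, 1) else sample(24:30, 1)
    repeat {
      cuts_true <- sort(sample(seq(min_seg, n - min_seg), k))
      if (k == 1 || diff(cuts_true) >= min_seg) break
    }
    levels <- cumsum(c(0, sample(c(-1, 1), k, replace = TRUE) *
                         runif(k, 1.2, 2)))
    x <- rnorm(n, rep(levels, diff(c(0, cuts_true, n))), 0.08)

    seg <- cbs_segment(x, alpha = 0.01, seed = case)
    got <- segment_cuts(seg)
    ok[case] <- length(got) == k
    if (ok[case])
      expect_equal(got, oracle_best_cuts(x, k), info = paste("case", case))

    pen <- 3 * 0.08^2 * log(n)
    expect_equal(segment_cuts(alt_segment(x, penalty = pen)),
                 oracle_penalized_cuts(x, pen), info = paste("case", case))
  }
  expect_gte(mean(ok), 0.9)
})

test_that("SEG output is 1-based inclusive", {
  x <- rep(0.5, 20)
  win <- toy_windows(20)
  seg <- alt_segment(x, win)
  tmp <- tempfile(fileext = ".seg")
  write_seg(seg, tmp, "s1")
  tab <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(tab$loc.start, 1)
  expect_equal(tab$loc.end, 20000)
  expect_equal(tab$num.mark, 20)
})
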