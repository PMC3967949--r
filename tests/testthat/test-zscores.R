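test_that("the z-score is the standardized deviation from the controls", {
  # controls whose region statistics are {90, 100, 110}; sample statistic 130
  ctrl <- cbind(rep(90, 4), rep(100, 4), rep(110, 4))
  expect_equal(zscore_region(1:4, rep(130, 4), ctrl), 3)
  expect_equal(zscore_region(1:4, rep(100, 4), ctrl), 0)

  # zero control SD: flagged NA, not +/-Inf
  same <- cbind(rep(1, 4), rep(1, 4), rep(1, 4))
  expect_true(is.na(zscore_region(1:4, rep(5, 4), same)))
  expect_error(zscore_region(1:2, rep(1, 2), cbind(1:2, 1:2)), "3 controls")
})

test_that("significance calls use strict +/-3 boundaries", {
  expect_equal(call_significance(c(3.5, -3, -7, 3, 2.99)),
               c("over", "neutral", "under", "neutral", "neutral"))
  expect_true(is.na(call_significance(NaN)))
  expect_true(is.na(call_significance(Inf)))
  expect_error(call_significance(1, threshold = 0), "threshold")
})

test_that("gene z-scores follow the 100 kb rule", {
  co <- small_cohort()
  raw <- simulate_counts(co$model, NULL, mean_depth = 65, seed = 555)$counts
  corrected <- gc_correct(median_normalize(raw), co$windows$gc)
  prof <- log2_ratios(corrected, co$panel)
  segs <- alt_segment(prof, co$windows)
  segs <- segmental_zscores(segs, corrected, co$controls_corrected,
                            usable = prof$usable)
  genes <- small_genes(co$model)
  gz <- gene_zscores(genes, co$windows, segs, corrected,
                     co$controls_corrected, usable = prof$usable)

  # short gene inherits its containing segment's z
  short <- gz[gz$name == "KRAS", ]
  expect_equal(short$derived_from, "segment")
  mid <- floor((short$start - 1 + short$end) / 2)
  seg_hit <- segs[segs$chrom == short$chrom & segs$start <= mid &
                    segs$end > mid, ]
  expect_equal(short$z, seg_hit$z)

  # long gene gets a direct region z; verify against a hand recomputation
  long <- gz[gz$name == "LONG", ]
  expect_equal(long$derived_from, "gene-region")
  idx <- which(co$windows$chrom == "chr2" &
                 co$windows$end > long$start - 1 &
                 co$windows$start < long$end & prof$usable)
  s <- mean(corrected[idx])
  cs <- colMeans(co$controls_corrected[idx, ])
  expect_equal(long$z, (s - mean(cs)) / sd(cs))

  expect_error(
    gene_zscores(data.frame(name = "NOPE", chrom = "chr99", start = 1,
                            end = 2e5),
                 co$windows, segs, corrected, co$controls_corrected),
    "outside")
})

test_that("a straddling short gene is assigned by its midpoint", {
  windows <- toy_windows(100)
  x <- c(rep(0, 50), rep(1, 50))
  segs <- alt_segment(x, windows, penalty = 0.5)
  ctrl <- matrix(rep(c(0, 0.01, -0.01), each = 100), 100, 3)
  segs <- segmental_zscores(segs, x, ctrl)
  # gene spans the boundary at 50,000 bp; midpoint is in the second segment
  gene <- data.frame(name = "STRADDLE", chrom = "chr1",
                     start = 49001, end = 52000)
  gz <- gene_zscores(gene, windows, segs, x, ctrl)
  expect_equal(gz$z, segs$z[2])
})

test_that("tumor fraction inverts the single-copy mixture", {
  seg <- data.frame(chrom = "chr1", n_windows = 200,
                    mean_log2 = log2(1.1), mean_ratio = 1.1)
  est <- estimate_tumor_fraction(seg)
  expect_equal(est$f_hat, 0.2, tolerance = 1e-12)
  expect_false(est$flagged)

  loss <- data.frame(chrom = "chr1", n_windows = 200,
                     mean_log2 = log2(0.9), mean_ratio = 0.9)
  expect_equal(estimate_tumor_fraction(loss)$f_hat, 0.2, tolerance = 1e-12)

  # balanced genome: flagged, f = 0
  flat <- data.frame(chrom = paste0("chr", 1:4), n_windows = 100,
                     mean_log2 = c(0.001, -0.002, 0, 0.004),
                     mean_ratio = c(1.001, 0.998, 1, 1.004))
  est <- estimate_tumor_fraction(flat)
  expect_true(est$flagged)
  expect_equal(est$f_hat, 0)

  # a strong but tiny segment does not qualify on span
  tiny <- rbind(flat, data.frame(chrom = "chr5", n_windows = 3,
                                 mean_log2 = 1, mean_ratio = 2))
  expect_true(estimate_tumor_fraction(tiny)$flagged)

  # extreme gains clamp to [0, 1]
  big <- data.frame(chrom = "chr1", n_windows = 300, mean_log2 = 1.5,
                    mean_ratio = 3)
  expect_equal(estimate_tumor_fraction(big)$f_hat, 1)
})

test_that("event z-scores increase with tumor fraction and copy number", {
  co <- small_cohort()
  idx <- which(co$windows$chrom == "chr4")[11:50]
  mean_z <- function(f, cn) {
    zs <- vapply(1:5, function(r) {
      truth <- truth_profile(data.frame(chrom = "chr4", start_window = 10,
                                        end_window = 50, copy_number = cn), f)
      raw <- simulate_counts(co$model, truth, mean_depth = 65,
                             seed = 9000 + r)$counts
      corrected <- gc_correct(median_normalize(raw), co$windows$gc)
      zscore_region(idx, corrected, co$controls_corrected)
    }, 0)
    mean(zs)
  }
  z_f <- c(mean_z(0.05, 4), mean_z(0.2, 4), mean_z(0.4, 4))
  expect_true(all(diff(z_f) > 0))
  z_cn <- c(mean_z(0.2, 3), mean_z(0.2, 6), mean_z(0.2, 12))
  expect_true(all(diff(z_cn) > 0))
})

test_that("count-basis and log2-basis agree on significant events", {
  co <- small_cohort()
  truth <- truth_profile(data.frame(chrom = "chr1", start_window = 20,
                                    end_window = 60, copy_number = 8), 0.2)
  raw <- simulate_counts(co$model, truth, mean_depth = 65, seed = 321)$counts
  corrected <- gc_correct(median_normalize(raw), co$windows$gc)
  prof <- log2_ratios(corrected, co$panel)
  ctrl_log2 <- vapply(seq_len(ncol(co$controls_corrected)), function(k)
    log2_ratios(co$controls_corrected[, k], co$panel)$log2,
    numeric(nrow(co$windows)))
  idx <- which(co$windows$chrom == "chr1")[21:60]
  z_counts <- zscore_region(idx, corrected, co$controls_corrected)
  z_log2 <- zscore_region(idx, prof$log2, ctrl_log2)
  expect_gt(z_counts, 3)
  expect_gt(z_log2, 3)
  expect_equal(sign(z_counts), sign(z_log2))
})
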