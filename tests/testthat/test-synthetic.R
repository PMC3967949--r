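test_that("reference model respects its construction contracts", {
  m <- make_reference_model(1, 100, seed = 7)
  expect_equal(nrow(m$windows), 100)
  expect_true(all(m$windows$gc >= 0.3 & m$windows$gc <= 0.7))
  expect_true(all(m$windows$weight > 0))
  expect_equal(mean(m$windows$weight), 1)

  m22 <- make_reference_model(22, 50, seed = 1)
  expect_equal(nrow(m22$windows), 1100)
  # genomic order within chromosomes
  for (ch in unique(m22$windows$chrom)) {
    w <- m22$windows[m22$windows$chrom == ch, ]
    expect_true(all(diff(w$start) > 0))
  }

  expect_identical(make_reference_model(3, 40, seed = 9),
                   make_reference_model(3, 40, seed = 9))
  expect_false(identical(make_reference_model(3, 40, seed = 9)$windows$gc,
                         make_reference_model(3, 40, seed = 10)$windows$gc))
  expect_error(make_reference_model(0, 50), "n_chromosomes")
  expect_error(make_reference_model(1, 5), "windows_per_chromosome")
})

test_that("simulated counts have the tumor/normal mixture mean structure", {
  m <- make_reference_model(1, 460, gc_spatial_smoothness = 0, seed = 3)
  event <- data.frame(chrom = "chr1", start_window = 0, end_window = 230,
                      copy_number = 4)

  # f = 0: no tumor signal; per-window mean ~ depth * weight * gc_bias
  s0 <- simulate_counts(m, truth_profile(event, 0), mean_depth = 200,
                        gc_bias = c(0, 0), dispersion = 0, seed = 11)
  expect_lt(abs(mean(s0$counts / (200 * m$windows$weight)) - 1), 0.02)

  # f = 0.2, CN = 4 -> event/background mean ratio 1.2 (closed-form mixture)
  s <- simulate_counts(m, truth_profile(event, 0.2), mean_depth = 65,
                       gc_bias = c(0, 0), seed = 12)
  ratio <- mean(s$counts[1:230] / m$windows$weight[1:230]) /
    mean(s$counts[231:460] / m$windows$weight[231:460])
  expect_lt(abs(ratio - expected_ratio(4, 0.2)), 0.03)

  # f = 0.1, CN = 10 -> ratio 1.4
  truth2 <- truth_profile(data.frame(chrom = "chr1", start_window = 0,
                                     end_window = 230, copy_number = 10), 0.1)
  s <- simulate_counts(m, truth2, mean_depth = 65, gc_bias = c(0, 0), seed = 13)
  ratio <- mean(s$counts[1:230] / m$windows$weight[1:230]) /
    mean(s$counts[231:460] / m$windows$weight[231:460])
  expect_lt(abs(ratio - expected_ratio(10, 0.1)), 0.035)

  expect_equal(expected_ratio(4, 0.2), 1.2)
  expect_equal(expected_ratio(10, 0.1), 1.4)
})

test_that("controls and f = 0 tumors are the same process; seeds reproduce", {
  m <- make_reference_model(2, 50, seed = 5)
  ev <- data.frame(chrom = "chr1", start_window = 10, end_window = 30,
                   copy_number = 8)
  ctrl <- simulate_counts(m, NULL, seed = 21)
  tum0 <- simulate_counts(m, truth_profile(ev, 0), seed = 21)
  expect_identical(ctrl$counts, tum0$counts)
  expect_identical(simulate_counts(m, NULL, seed = 21)$counts, ctrl$counts)

  bad <- data.frame(chrom = "chr1", start_window = 10, end_window = 60,
                    copy_number = 4)
  expect_error(simulate_counts(m, truth_profile(bad, 0.2), seed = 1),
               "bounds")
  expect_error(simulate_counts(m, truth_profile(
    data.frame(chrom = "chr9", start_window = 0, end_window = 5,
               copy_number = 4), 0.2), seed = 1), "not in model")
})

test_that("truth profiles validate their invariants", {
  expect_error(truth_profile(tumor_fraction = 1.5), "tumor_fraction")
  overlapping <- data.frame(chrom = "chr1", start_window = c(0, 5),
                            end_window = c(10, 15), copy_number = 3)
  expect_error(truth_profile(overlapping, 0.1), "overlap")
  expect_error(truth_profile(data.frame(chrom = "chr1", start_window = 0,
                                        end_window = 5, copy_number = 2.5),
                             0.1), "integer")
})

test_that("simulated pileups track the true VAF", {
  p <- simulate_pileup(0, 1000, base_error_rate = 0, seed = 1)
  expect_equal(sum(p$allele == "alt"), 0)
  p <- simulate_pileup(1, 500, base_error_rate = 0, seed = 2)
  expect_equal(sum(p$allele == "alt"), 500)

  # VAF 2% at 10,000x, no error: alt count within the binomial 99% interval
  p <- simulate_pileup(0.02, 10000, base_error_rate = 0, seed = 3)
  expect_gte(sum(p$allele == "alt"), qbinom(0.005, 10000, 0.02))
  expect_lte(sum(p$allele == "alt"), qbinom(0.995, 10000, 0.02))

  expect_error(simulate_pileup(0.1, 0), "depth")
  expect_error(simulate_pileup(1.2, 10), "true_vaf")
})

test_that("count tables and truth sets round-trip through TSV", {
  m <- make_reference_model(2, 20, seed = 8)
  s <- simulate_counts(m, NULL, seed = 9)
  tmp <- tempfile(fileext = ".tsv")
  write_window_counts(s, m, tmp)
  back <- read_window_counts(tmp)
  expect_identical(back$counts, s$counts)
  expect_equal(back$windows$start, m$windows$start)

  tr <- truth_profile(data.frame(chrom = "chr1", start_window = 2,
                                 end_window = 9, copy_number = 6), 0.15)
  tpath <- tempfile(fileext = ".tsv")
  write_truth(tr, tpath, seed = 4)
  meta <- jsonlite::read_json(paste0(tpath, ".json"))
  expect_equal(meta$tumor_fraction, 0.15)
})
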