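test_that("GC correction removes injected bias and little else", {
  set.seed(17)
  gc <- runif(2000, 0.35, 0.65)

  # no bias to remove: corrected stays close to the input
  flat <- rpois(2000, 80) / 80
  corr <- gc_correct(flat, gc)
  expect_lt(max(abs(corr - flat) / flat), 0.02)
  expect_equal(mean(corr), mean(flat), tolerance = 1e-6)

  # quadratic bias with |r| > 0.5 is reduced to |r| < 0.05
  bias <- 1 + 1.2 * (gc - 0.5) - 6 * (gc - 0.5)^2
  x <- rpois(2000, 80 * bias) / 80
  expect_gt(abs(cor(x, gc)), 0.5)
  corr <- gc_correct(x, gc)
  expect_lt(abs(cor(corr, gc)), 0.05)
  expect_equal(mean(corr), mean(x), tolerance = 1e-6)

  # idempotence: a second pass changes < 0.5% RMS
  twice <- gc_correct(corr, gc)
  expect_lt(sqrt(mean((twice - corr)^2)) / mean(corr), 0.005)

  expect_warning(out <- gc_correct(x, rep(0.5, 2000)), "identical")
  expect_identical(out, x)
  expect_error(gc_correct(x, gc[-1]), "lengths")
  expect_error(gc_correct(x, gc, lowess_fraction = 0), "lowess_fraction")
})

test_that("control panels summarize per-window mean and n-1 SD", {
  expect_error(build_control_panel(cbind(1:4, 1:4)), "3 controls")

  same <- cbind(rep(1, 5), rep(1, 5), rep(1, 5))
  p <- build_control_panel(same)
  expect_true(all(p$sd == 0))
  expect_true(all(!p$usable))

  p <- build_control_panel(list(c(0.9, 2), c(1.0, 2), c(1.1, 2)))
  expect_equal(p$mean[1], 1)
  expect_equal(p$sd[1], 0.1)   # n-1 denominator
  expect_false(p$usable[2])

  # 20 simulated controls: per-window mean within 3 SE of the generative truth
  m <- make_reference_model(1, 300, seed = 23)
  mat <- vapply(1:20, function(k)
    simulate_counts(m, NULL, mean_depth = 200, gc_bias = c(0, 0),
                    seed = 2300 + k)$counts / 200,
    numeric(300))
  p <- build_control_panel(mat)
  se <- p$sd / sqrt(20)
  covered <- abs(p$mean - m$windows$weight) <= 3 * se
  expect_gt(mean(covered), 0.95)
})

test_that("log2-ratios are zero at the panel mean and additive in doublings", {
  panel <- build_control_panel(cbind(rep(1, 50), rep(1.05, 50), rep(0.95, 50)))
  prof <- log2_ratios(panel$mean, panel, pseudocount = 0, center = FALSE)
  expect_true(all(abs(prof$log2) < 1e-12))

  doubled <- panel$mean
  doubled[10] <- 2 * panel$mean[10]
  prof <- log2_ratios(doubled, panel, pseudocount = 0, center = FALSE)
  expect_equal(prof$log2[10], 1)
  # median recentring leaves a single doubled window's ratio at 1
  prof_c <- log2_ratios(doubled, panel, pseudocount = 0)
  expect_equal(prof_c$log2[10], 1)

  expect_error(log2_ratios(rep(1, 10), panel), "grids")
})

test_that("held-out controls score near zero against the panel", {
  co <- small_cohort()
  raw <- simulate_counts(co$model, NULL, mean_depth = 65, seed = 777)$counts
  corrected <- gc_correct(median_normalize(raw), co$windows$gc)
  prof <- log2_ratios(corrected, co$panel)
  m <- mean(prof$log2[prof$usable])
  se <- sd(prof$log2[prof$usable]) / sqrt(sum(prof$usable))
  expect_lt(abs(m), 3 * se + 1e-3)
})

test_that("log2-ratios are invariant to sequencing depth (scale equivariance)", {
  co <- small_cohort()
  raw <- simulate_counts(co$model, NULL, mean_depth = 65, seed = 778)$counts
  pipe <- function(r) {
    log2_ratios(gc_correct(median_normalize(r), co$windows$gc), co$panel)$log2
  }
  expect_equal(pipe(raw), pipe(raw * 7), tolerance = 1e-10)
})

test_that("an injected CN=4 event at f=0.2 lands near log2(1.2)", {
  # study-scale genome so the event is a realistic ~1% of windows; tolerance
  # is ~3 SE of the 60-window mean at this depth
  model <- make_reference_model(22, 230, seed = 61)
  ctl <- vapply(1:6, function(k)
    gc_correct(median_normalize(
      simulate_counts(model, NULL, mean_depth = 65, seed = 6100 + k)$counts),
      model$windows$gc),
    numeric(nrow(model$windows)))
  panel <- build_control_panel(ctl)
  truth <- truth_profile(data.frame(chrom = "chr3", start_window = 10,
                                    end_window = 70, copy_number = 4), 0.2)
  raw <- simulate_counts(model, truth, mean_depth = 65, seed = 779)$counts
  corrected <- gc_correct(median_normalize(raw), model$windows$gc)
  prof <- log2_ratios(corrected, panel)
  idx <- which(model$windows$chrom == "chr3")[11:70]
  expect_lt(abs(mean(prof$log2[idx]) - log2(1.2)), 0.08)
})

test_that("panels round-trip through their TSV serialization", {
  co <- small_cohort()
  tmp <- tempfile(fileext = ".tsv")
  write_panel(co$panel, co$windows, tmp)
  back <- read_panel(tmp)
  expect_equal(back$n_controls, co$panel$n_controls)
  expect_equal(back$mean, co$panel$mean, tolerance = 1e-10)
  expect_equal(back$usable, co$panel$usable)
})
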