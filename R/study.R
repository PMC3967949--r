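#' @name study
#' @title Simulation experiments at the study's conditions
#'
#' @description
#' These functions encode the conditions of the shallow plasma-sequencing
#' setting the package targets — a 22-autosome fixture genome of 230 windows
#' per chromosome (a 1/10-scale stand-in for the 50,000-window hg19 grid),
#' ~65 reads per window (0.16x coverage in 50,000-window space), negative
#' binomial counts with dispersion 0.003, and a 20-sample non-cancer control
#' panel — and run the calibration / power / recovery experiments that
#' characterize the pipeline: null z-score calibration, focal-amplification
#' and arm-level polysomy detection power, tumor-fraction recovery, the
#' low-ctDNA guard, GC-correction quality, and deep-sequencing variant
#' thresholding. Each returns the measured rates so tests and reports can
#' assert against them.
NULL

STUDY_DEPTH <- 65
STUDY_DISPERSION <- 0.003
STUDY_N_CONTROLS <- 20L

#' @rdname study
#' @param seed Integer seed; every source of randomness in a study function is
#'   derived from it.
#' @return `study_cohort()`: list with `model`, `windows`, `panel`,
#'   `controls_corrected`.
#' @param n_controls Number of control plasma samples in the panel.
#' @export
study_cohort <- function(seed = 1, n_controls = STUDY_N_CONTROLS) {
  model <- make_reference_model(22L, 230L, seed = seed)
  control_raw <- lapply(seq_len(n_controls), function(k) {
    simulate_counts(model, NULL, mean_depth = STUDY_DEPTH,
                    dispersion = STUDY_DISPERSION, seed = seed * 1000L + k)$counts
  })
  pan <- panel_from_raw_controls(model$windows, control_raw,
                                 default_params()$lowess_fraction)
  list(model = model, windows = model$windows, panel = pan$panel,
       controls_corrected = pan$controls_corrected)
}

#' Therapy-relevant gene fixture for the synthetic genome
#'
#' Synthetic stand-in coordinates: the four anti-EGFR-relevant genes with
#' their true lengths (KRAS 45,674 bp; MET 125,982 bp; ERBB2 42,513 bp;
#' EGFR 192,611 bp) placed at deterministic positions in the scaled fixture
#' genome — KRAS inside the canonical focal-event region on the chromosome-12
#' analog. Genes under 100 kb (KRAS, ERBB2) exercise the segment-derived
#' z-score rule; MET and EGFR are long enough for direct gene-region z-scores.
#'
#' @param model A `reference_model` (fixture-scale).
#' @return Gene data.frame (`name`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @export
study_genes <- function(model) {
  ws <- model$window_size
  gene <- function(name, chrom, window, len) {
    start <- window * ws + 5000 + 1
    data.frame(name = name, chrom = chrom, start = start,
               end = start + len - 1, stringsAsFactors = FALSE)
  }
  rbind(
    gene("KRAS", "chr12", 115, 45674),
    gene("MET", "chr7", 150, 125982),
    gene("ERBB2", "chr17", 80, 42513),
    gene("EGFR", "chr7", 40, 192611)
  )
}

# n short (<100 kb) synthetic gene regions spread deterministically over the
# genome, for null-calibration experiments.
study_null_genes <- function(model, n = 50L) {
  ws <- model$window_size
  m <- model$windows_per_chromosome
  i <- seq_len(n)
  chrom <- paste0("chr", ((i - 1) %% model$n_chromosomes) + 1)
  win <- (17 * i) %% (m - 2) + 1
  start <- win * ws + 3000 + 1
  data.frame(name = sprintf("G%03d", i), chrom = chrom, start = start,
             end = start + 50000 - 1, stringsAsFactors = FALSE)
}

study_analyze <- function(cohort, truth, genes, seed) {
  raw <- simulate_counts(cohort$model, truth, mean_depth = STUDY_DEPTH,
                         dispersion = STUDY_DISPERSION, seed = seed)$counts
  analyze_sample(cohort$windows, raw, cohort$panel,
                 cohort$controls_corrected, genes = genes,
                 params = list(seed = seed))
}

# z of the consensus segment containing a window-index midpoint on `chrom`.
segment_z_at <- function(res, windows, chrom, mid_window) {
  g0 <- which(windows$chrom == chrom)[1] - 1  # chrom-local -> global index
  gmid <- g0 + mid_window
  seg <- res$segments
  hit <- seg$chrom == chrom & seg$start_window < gmid & seg$end_window >= gmid
  if (!any(hit)) return(NA_real_)
  seg$z[which(hit)[1]]
}

# Are all true chrom-local breakpoints matched by a consensus boundary within
# `tol` windows?
breakpoints_recovered <- function(res, windows, chrom, edges, tol = 2) {
  g0 <- which(windows$chrom == chrom)[1] - 1
  seg <- res$segments[res$segments$chrom == chrom, , drop = FALSE]
  bounds <- unique(c(seg$start_window, seg$end_window)) - g0
  all(vapply(edges, function(e) any(abs(bounds - e) <= tol), TRUE))
}

#' @rdname study
#' @param n_null Held-out null (non-cancer) samples to score.
#' @param n_regions Synthetic gene regions scored per null sample.
#' @return `study_null_calibration()`: list with `n_tests`, `n_exceed`,
#'   `fraction` of regions with |z| > 3, and the per-sample exceedance counts.
#' @export
study_null_calibration <- function(seed = 1, n_controls = STUDY_N_CONTROLS,
                                   n_null = 20L, n_regions = 50L) {
  cohort <- study_cohort(seed, n_controls)
  genes <- study_null_genes(cohort$model, n_regions)
  per_sample <- vapply(seq_len(n_null), function(k) {
    res <- study_analyze(cohort, NULL, genes, seed = seed * 2000L + k)
    sum(abs(res$gene_z$z) > 3, na.rm = TRUE)
  }, 0L)
  n_tests <- n_null * n_regions
  list(n_tests = n_tests, n_exceed = sum(per_sample),
       fraction = sum(per_sample) / n_tests, per_sample = per_sample)
}

#' @rdname study
#' @param n_reps Number of simulated tumor samples.
#' @param f Tumor fraction of the simulated samples.
#' @param cn Tumor copy number of the event.
#' @param span Event width in windows.
#' @return `study_focal_amplification()`: list with `z` (per-replicate
#'   segmental z at the event), `power` (fraction with z > 3),
#'   `breakpoint_rate` (fraction with all event edges recovered within +/-2
#'   windows by the consensus).
#' @export
study_focal_amplification <- function(seed = 2, n_reps = 50L, f = 0.1,
                                      cn = 10L, span = 30L) {
  cohort <- study_cohort(seed)
  start <- 100L
  truth <- truth_profile(
    data.frame(chrom = "chr12", start_window = start,
               end_window = start + span, copy_number = cn), f)
  z <- numeric(n_reps)
  bp <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    res <- study_analyze(cohort, truth, NULL, seed = seed * 3000L + r)
    z[r] <- segment_z_at(res, cohort$windows, "chr12", start + span %/% 2)
    bp[r] <- breakpoints_recovered(res, cohort$windows, "chr12",
                                   c(start, start + span))
  }
  list(z = z, power = mean(z > 3, na.rm = TRUE), breakpoint_rate = mean(bp))
}

#' @rdname study
#' @return `study_arm_polysomy()`: list with `z` per replicate and `power`.
#' @export
study_arm_polysomy <- function(seed = 3, n_reps = 50L, f = 0.2, cn = 3L) {
  cohort <- study_cohort(seed)
  arm_end <- cohort$model$windows_per_chromosome %/% 2  # "12p": proximal half
  truth <- truth_profile(
    data.frame(chrom = "chr12", start_window = 0L, end_window = arm_end,
               copy_number = cn), f)
  z <- vapply(seq_len(n_reps), function(r) {
    res <- study_analyze(cohort, truth, NULL, seed = seed * 3000L + r)
    segment_z_at(res, cohort$windows, "chr12", arm_end %/% 2)
  }, 0)
  list(z = z, power = mean(z > 3, na.rm = TRUE))
}

#' @rdname study
#' @param f_values Tumor fractions at which recovery is measured.
#' @return `study_tumor_fraction_recovery()`: data.frame with one row per run
#'   (`f`, `f_hat`, `error`, `flagged`) plus attribute `within_05` (fraction of
#'   runs with |error| <= 0.05). The simulated event is a single-copy gain of
#'   the whole chromosome-12 analog (at fixture scale one chromosome has fewer
#'   windows than a real mid-size arm has on the 50,000-window grid).
#' @export
study_tumor_fraction_recovery <- function(seed = 4,
                                          f_values = c(0.1, 0.2, 0.3, 0.5),
                                          n_reps = 20L) {
  cohort <- study_cohort(seed)
  m <- cohort$model$windows_per_chromosome
  rows <- list()
  for (fi in seq_along(f_values)) {
    f <- f_values[fi]
    truth <- truth_profile(
      data.frame(chrom = "chr12", start_window = 0L, end_window = m,
                 copy_number = 3L), f)
    for (r in seq_len(n_reps)) {
      res <- study_analyze(cohort, truth, NULL,
                           seed = seed * 4000L + fi * 100L + r)
      tf <- res$tumor_fraction
      rows[[length(rows) + 1]] <- data.frame(
        f = f, f_hat = tf$f_hat, error = tf$f_hat - f, flagged = tf$flagged)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "within_05") <- mean(abs(out$error) <= 0.05)
  out
}

#' @rdname study
#' @return `study_low_ctdna_guard()`: list with per-replicate `clean` (no gene
#'   |z| > 3), `flagged` (tumor fraction flagged low), `clean_rate`,
#'   `flagged_rate`, and `guard_rate` (both jointly). The truth profile is the
#'   arm-level CRC constellation of a low-ctDNA patient (8p loss, 8q/20q
#'   gains, 18q loss) — none of the scored therapy genes carries a true event,
#'   so any |z| > 3 gene call is a false alarm.
#' @export
study_low_ctdna_guard <- function(seed = 5, n_reps = 50L, f = 0.02) {
  cohort <- study_cohort(seed)
  m <- cohort$model$windows_per_chromosome
  half <- m %/% 2
  events <- rbind(
    data.frame(chrom = "chr8", start_window = 0L, end_window = half,
               copy_number = 1L),
    data.frame(chrom = "chr8", start_window = half, end_window = m,
               copy_number = 3L),
    data.frame(chrom = "chr20", start_window = half, end_window = m,
               copy_number = 3L),
    data.frame(chrom = "chr18", start_window = half, end_window = m,
               copy_number = 1L)
  )
  truth <- truth_profile(events, f)
  genes <- study_genes(cohort$model)
  clean <- flagged <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    res <- study_analyze(cohort, truth, genes, seed = seed * 3000L + r)
    clean[r] <- !any(abs(res$gene_z$z) > 3, na.rm = TRUE)
    flagged[r] <- res$tumor_fraction$flagged
  }
  list(clean = clean, flagged = flagged, clean_rate = mean(clean),
       flagged_rate = mean(flagged), guard_rate = mean(clean & flagged))
}

#' @rdname study
#' @return `study_gc_correction()`: list with `r_before`/`r_after` (Pearson
#'   correlation of counts with GC before/after correction on a strongly
#'   biased sample) and `idempotence_rms` (relative RMS change of a second
#'   correction pass).
#' @export
study_gc_correction <- function(seed = 6) {
  model <- make_reference_model(22L, 230L, seed = seed)
  raw <- simulate_counts(model, NULL, mean_depth = STUDY_DEPTH,
                         gc_bias = c(1.5, -8), dispersion = STUDY_DISPERSION,
                         seed = seed + 1)$counts
  x <- median_normalize(raw)
  gc <- model$windows$gc
  corrected <- gc_correct(x, gc)
  twice <- gc_correct(corrected, gc)
  list(r_before = cor(x, gc), r_after = cor(corrected, gc),
       idempotence_rms = sqrt(mean((twice - corrected)^2)) / mean(corrected))
}

#' @rdname study
#' @param depth Pileup depth per replicate.
#' @param true_vaf Simulated variant allele fraction.
#' @param base_error_rate Sequencing error rate.
#' @return `study_deep_variants()`: list with `called_rate` (fraction of
#'   replicates where the variant at `true_vaf` is called after MAPQ/baseQ
#'   filtering) and `false_rate` (same with true VAF 0 — sequencing error
#'   only).
#' @export
study_deep_variants <- function(seed = 7, n_reps = 100L, depth = 10000L,
                                true_vaf = 0.02, base_error_rate = 0.001) {
  run <- function(vaf, s) {
    p <- simulate_pileup(vaf, depth, base_error_rate, seed = s)
    p <- mask_bases(filter_reads(p))
    call_mutation(p)$status == "called"
  }
  called <- vapply(seq_len(n_reps), function(r)
    run(true_vaf, seed * 5000L + r), TRUE)
  false_pos <- vapply(seq_len(n_reps), function(r)
    run(0, seed * 6000L + r), TRUE)
  list(called_rate = mean(called), false_rate = mean(false_pos))
}
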