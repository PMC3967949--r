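#' Build a synthetic reference model of the windowed genome
#'
#' Creates the window-space abstraction the pipeline operates in: an ordered
#' set of fixed genomic windows per chromosome, each with a GC fraction and a
#' relative mappability weight. GC values follow a smooth (AR(1)) spatial
#' profile constrained to \[0.3, 0.7\], as in the GC range that real
#' equal-mappability bins occupy; mappability weights are mildly variable with
#' unit mean. The default dimensions (22 autosomes x 230 windows, ~5,060
#' windows) are a 1/10-scale stand-in for the 50,000-window grid used on the
#' full genome.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param windows_per_chromosome Windows per chromosome (>= 10).
#' @param gc_spatial_smoothness AR(1) coefficient in [0, 1) controlling how
#'   slowly GC drifts along a chromosome.
#' @param seed Integer seed; identical arguments and seed give a bitwise
#'   identical model.
#' @param window_size Width in bp of each synthetic window (60 kb by default,
#'   close to the ~62 kb mean width of a 50,000-window hg19 grid).
#' @return An object of class `reference_model`: a list with `windows`
#'   (data.frame with `chrom`, `start`, `end` 0-based half-open, `gc`,
#'   `weight`), `window_size` and the call parameters.
#' @examples
#' m <- make_reference_model(2, 50, seed = 1)
#' range(m$windows$gc)
#' @export
make_reference_model <- function(n_chromosomes = 22L,
                                 windows_per_chromosome = 230L,
                                 gc_spatial_smoothness = 0.9,
                                 seed = NULL,
                                 window_size = 60000L) {
  stop_if_not(n_chromosomes >= 1, "n_chromosomes must be >= 1")
  stop_if_not(windows_per_chromosome >= 10, "windows_per_chromosome must be >= 10")
  stop_if_not(gc_spatial_smoothness >= 0 && gc_spatial_smoothness < 1,
              "gc_spatial_smoothness must be in [0, 1)")
  n_chromosomes <- as.integer(n_chromosomes)
  m <- as.integer(windows_per_chromosome)
  rho <- gc_spatial_smoothness
  windows <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
      z <- numeric(m)
      z[1] <- rnorm(1)
      if (m > 1) {
        eps <- rnorm(m - 1, sd = sqrt(1 - rho^2))
        for (t in 2:m) z[t] <- rho * z[t - 1] + eps[t - 1]
      }
      gc <- 0.5 + 0.2 * tanh(z / 2.5)   # strictly inside [0.3, 0.7]
      w <- exp(rnorm(m, sd = 0.05))
      data.frame(
        chrom = paste0("chr", ci),
        start = as.numeric(0:(m - 1)) * window_size,
        end = as.numeric(1:m) * window_size,
        gc = gc,
        weight = w,
        stringsAsFactors = FALSE
      )
    }))
  })
  windows$weight <- windows$weight / mean(windows$weight)
  rownames(windows) <- NULL
  structure(
    list(windows = windows, window_size = window_size,
         n_chromosomes = n_chromosomes,
         windows_per_chromosome = m, seed = seed),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat("reference_model:", x$n_chromosomes, "chromosomes x",
      x$windows_per_chromosome, "windows (",
      nrow(x$windows), "windows total ), window size",
      x$window_size, "bp\n")
  invisible(x)
}

#' Define a simulated tumor copy-number truth profile
#'
#' Events are clonal copy-number states of the tumor genome (background copy
#' number 2) present in the plasma at tumor fraction `f`; the expected relative
#' coverage of a window with tumor copy number CN is `(2(1-f) + CN*f)/2`.
#' Window indices are 0-based half-open within their chromosome.
#'
#' @param events data.frame with columns `chrom`, `start_window`, `end_window`
#'   (0-based half-open), `copy_number` (non-negative integer). May be empty.
#' @param tumor_fraction Proportion of cfDNA derived from the tumor, in \[0, 1\].
#' @return Object of class `truth_profile`.
#' @examples
#' truth_profile(data.frame(chrom = "chr12", start_window = 35,
#'                          end_window = 65, copy_number = 10), 0.1)
#' @export
truth_profile <- function(events = NULL, tumor_fraction = 0) {
  stop_if_not(tumor_fraction >= 0 && tumor_fraction <= 1,
              "tumor_fraction must be in [0, 1]")
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(chrom = character(), start_window = integer(),
                         end_window = integer(), copy_number = integer(),
                         stringsAsFactors = FALSE)
  }
  need <- c("chrom", "start_window", "end_window", "copy_number")
  stop_if_not(all(need %in% names(events)),
              "events needs columns chrom, start_window, end_window, copy_number")
  stop_if_not(all(events$copy_number >= 0 & events$copy_number == round(events$copy_number)),
              "copy_number must be a non-negative integer")
  stop_if_not(all(events$start_window < events$end_window),
              "events must have start_window < end_window")
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, , drop = FALSE]
    e <- e[order(e$start_window), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start_window[-1] < e$end_window[-nrow(e)]))
      stop("events on ", ch, " overlap", call. = FALSE)
  }
  structure(list(events = events, tumor_fraction = tumor_fraction),
            class = "truth_profile")
}

#' Expected coverage ratio of a copy-number event in plasma
#'
#' At tumor fraction `f`, a region with tumor copy number `cn` on a diploid
#' background has expected relative coverage `(2(1-f) + cn*f)/2 =
#' 1 + f*(cn-2)/2`.
#'
#' @param cn Tumor copy number (non-negative).
#' @param f Tumor fraction in \[0, 1\].
#' @return Expected ratio of event coverage to diploid background coverage.
#' @examples
#' expected_ratio(4, 0.2)   # 1.2
#' expected_ratio(10, 0.1)  # 1.4
#' @export
expected_ratio <- function(cn, f) (2 * (1 - f) + cn * f) / 2

# Per-window copy-number mixture factor for a model + truth profile.
cn_mixture_factor <- function(model, truth) {
  w <- model$windows
  fac <- rep(1, nrow(w))
  if (is.null(truth)) return(fac)
  ev <- truth$events
  f <- truth$tumor_fraction
  if (nrow(ev) == 0 || f == 0) return(fac)
  for (r in seq_len(nrow(ev))) {
    sel <- which(w$chrom == ev$chrom[r])
    if (length(sel) == 0)
      stop("event chromosome ", ev$chrom[r], " not in model", call. = FALSE)
    if (ev$end_window[r] > length(sel))
      stop("event on ", ev$chrom[r], " exceeds chromosome bounds", call. = FALSE)
    idx <- sel[(ev$start_window[r] + 1):ev$end_window[r]]
    fac[idx] <- expected_ratio(ev$copy_number[r], f)
  }
  fac
}

# Quadratic GC bias curve normalized to unit mean over the model's windows.
gc_bias_curve <- function(gc, coef) {
  b <- 1 + coef[1] * (gc - 0.5) + coef[2] * (gc - 0.5)^2
  b <- pmax(b, 0.05)
  b / mean(b)
}

#' Simulate per-window cfDNA read counts
#'
#' Draws window counts from a negative-binomial distribution (Poisson when
#' `dispersion = 0`) with mean
#' `depth * weight * gc_bias(gc) * (1 + f*(CN-2)/2)`, i.e. an overdispersed
#' sampling model with a smooth unimodal GC bias (quadratic in GC, unit mean)
#' and a tumor/normal mixture signal. A control sample is `truth = NULL`.
#'
#' @param model A [make_reference_model()] object.
#' @param truth A [truth_profile()] or NULL for a control.
#' @param mean_depth Mean reads per window (default 65, the per-window depth of
#'   a 0.16x genome in 50,000-window space).
#' @param gc_bias Length-2 numeric: linear and quadratic coefficients of the GC
#'   bias in `(gc - 0.5)`; `c(0, 0)` disables the bias.
#' @param dispersion Negative-binomial dispersion (`variance = mu + dispersion
#'   * mu^2`); 0 gives Poisson counts.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `sim_sample`: list with integer `counts` (one per
#'   model window), `truth`, and `seed`.
#' @examples
#' m <- make_reference_model(1, 100, seed = 1)
#' s <- simulate_counts(m, mean_depth = 50, seed = 2)
#' mean(s$counts)
#' @export
simulate_counts <- function(model, truth = NULL, mean_depth = 65,
                            gc_bias = c(0.3, -2), dispersion = 0.003,
                            seed = NULL) {
  stop_if_not(inherits(model, "reference_model"), "model must be a reference_model")
  stop_if_not(mean_depth > 0, "mean_depth must be > 0")
  stop_if_not(dispersion >= 0, "dispersion must be >= 0")
  if (!is.null(truth))
    stop_if_not(inherits(truth, "truth_profile"), "truth must be a truth_profile")
  w <- model$windows
  mu <- mean_depth * w$weight * gc_bias_curve(w$gc, gc_bias) *
    cn_mixture_factor(model, truth)
  counts <- with_seed(seed, {
    if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else rpois(length(mu), lambda = mu)
  })
  structure(list(counts = as.integer(counts), truth = truth, seed = seed),
            class = "sim_sample")
}

#' Simulate a targeted deep-sequencing pileup at one locus
#'
#' Generates `depth` read bases whose allele is alternate with probability
#' `true_vaf`, then flipped (sequencing error) with probability
#' `base_error_rate`; mapping and base qualities are drawn from the supplied
#' distributions. The defaults emulate a MiSeq amplicon pileup with a small
#' fraction of low-MAPQ alignments and low-Phred bases, so the standard
#' MAPQ < 15 / Phred < 20 filters have something to remove.
#'
#' @param true_vaf True variant allele fraction in \[0, 1\].
#' @param depth Number of read bases (>= 1).
#' @param base_error_rate Per-base allele flip probability.
#' @param mapq_distribution,baseq_distribution Either a numeric vector sampled
#'   from with replacement, or a `function(n)` returning `n` qualities.
#' @param seed Integer seed.
#' @return data.frame of class `locus_pileup` with columns `allele` ("ref" or
#'   "alt"), `mapq`, `baseq`, `masked` (all FALSE initially).
#' @examples
#' p <- simulate_pileup(0.02, 1000, base_error_rate = 0, seed = 1)
#' table(p$allele)
#' @export
simulate_pileup <- function(true_vaf, depth, base_error_rate = 0.001,
                            mapq_distribution = c(rep(60, 90), rep(40, 4),
                                                  rep(14, 4), rep(5, 2)),
                            baseq_distribution = c(rep(37, 80), rep(30, 10),
                                                   rep(22, 5), rep(15, 5)),
                            seed = NULL) {
  stop_if_not(true_vaf >= 0 && true_vaf <= 1, "true_vaf must be in [0, 1]")
  stop_if_not(depth >= 1, "depth must be >= 1")
  draw <- function(dist, n) {
    if (is.function(dist)) dist(n) else sample(dist, n, replace = TRUE)
  }
  with_seed(seed, {
    is_alt <- runif(depth) < true_vaf
    err <- runif(depth) < base_error_rate
    allele <- ifelse(xor(is_alt, err), "alt", "ref")
    out <- data.frame(
      allele = allele,
      mapq = as.integer(draw(mapq_distribution, depth)),
      baseq = as.integer(draw(baseq_distribution, depth)),
      masked = FALSE,
      stringsAsFactors = FALSE
    )
    class(out) <- c("locus_pileup", "data.frame")
    out
  })
}

#' Write a simulated sample as a window-count table
#'
#' Writes a TSV with columns `chrom`, `start`, `end`, `gc`, `count` (the format
#' consumed by the pipeline's count-table input path).
#'
#' @param sample A `sim_sample` or an integer count vector.
#' @param model The `reference_model` the counts live on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_window_counts <- function(sample, model, path) {
  counts <- if (inherits(sample, "sim_sample")) sample$counts else sample
  w <- model$windows
  stop_if_not(length(counts) == nrow(w), "counts length must match model windows")
  out <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                    gc = w$gc, count = counts)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth profile as TSV plus a JSON sidecar
#'
#' The events go to `<path>` as TSV (`chrom`, `start_window`, `end_window`,
#' `copy_number`); tumor fraction and seed go to `<path>.json`.
#'
#' @param truth A [truth_profile()].
#' @param path Output TSV path.
#' @param seed Seed to record alongside the tumor fraction.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NULL) {
  write.table(truth$events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tumor_fraction = truth$tumor_fraction, seed = seed),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}
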