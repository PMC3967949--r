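#' Default pipeline parameters
#'
#' The analysis defaults: 50,000 genome-wide windows, LOWESS span 0.3, CBS
#' alpha 0.01 with 1000 permutations and minimum segment width 2, gain/loss
#' plotting thresholds +0.2/-0.2, z significance threshold 3.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    n_windows = 50000L,
    lowess_fraction = 0.3,
    alpha = 0.01,
    n_permutations = 1000L,
    min_width = 2L,
    undo_sd = 1,
    merge_tol = 0.05,
    gain_threshold = 0.2,
    loss_threshold = -0.2,
    z_threshold = 3,
    min_span_fraction = 0.01,
    noise_floor = 0.03,
    se_mult = 3.5,
    seed = NULL
  )
}

#' Analyze one sample against a control panel
#'
#' The single-sample engine behind [run_pipeline()]: median normalization, GC
#' LOWESS correction, log2-ratios against the panel, CBS + penalized
#' segmentation + consensus, segment classification, segmental and gene
#' z-scores (counts basis), and tumor-fraction estimation.
#'
#' @param windows Window grid data.frame with a `gc` column.
#' @param raw Raw per-window counts of the sample.
#' @param panel A [build_control_panel()] object on the grid.
#' @param controls_corrected Matrix (windows x controls) of the controls'
#'   GC-corrected normalized counts (the z-score basis).
#' @param genes Optional gene table (`name`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param params Parameter list; see [default_params()]. Unset entries fall
#'   back to the defaults.
#' @return List with `normalized`, `corrected`, `profile` (log2), `segments`
#'   (consensus, classified, with z), `cbs`, `alt`, `gene_z`,
#'   `tumor_fraction`, `log` (character vector of stage messages).
#' @export
analyze_sample <- function(windows, raw, panel, controls_corrected,
                           genes = NULL, params = list()) {
  p <- utils::modifyList(default_params(), params)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  normalized <- median_normalize(raw)
  corrected <- gc_correct(normalized, windows$gc, p$lowess_fraction)
  say("normalized ", length(raw), " windows; median raw count ", median(raw))

  profile <- log2_ratios(corrected, panel)
  say("log2-ratios computed; ", sum(!profile$usable), " windows unusable")

  seg_cbs <- cbs_segment(profile, windows, alpha = p$alpha,
                         n_permutations = p$n_permutations,
                         min_width = p$min_width, undo_sd = p$undo_sd,
                         seed = p$seed)
  seg_alt <- alt_segment(profile, windows, min_width = p$min_width)
  segments <- consensus_segments(seg_cbs, seg_alt, profile, windows,
                                 merge_tol = p$merge_tol)
  segments <- classify_segments(segments, p$gain_threshold, p$loss_threshold)
  say("segmentation: CBS ", nrow(seg_cbs), ", penalized ", nrow(seg_alt),
      ", consensus ", nrow(segments), " segments")

  segments <- segmental_zscores(segments, corrected, controls_corrected,
                                usable = profile$usable,
                                threshold = p$z_threshold)
  gene_z <- NULL
  if (!is.null(genes) && nrow(genes) > 0) {
    gene_z <- gene_zscores(genes, windows, segments, corrected,
                           controls_corrected, usable = profile$usable,
                           threshold = p$z_threshold)
    say("gene z-scores for ", nrow(genes), " genes")
  }
  tf <- estimate_tumor_fraction(
    segments, window_sd = estimate_window_sd(profile$log2),
    min_span_fraction = p$min_span_fraction, noise_floor = p$noise_floor,
    se_mult = p$se_mult
  )
  say("tumor fraction estimate ", format(tf$f_hat, digits = 3),
      if (tf$flagged) " (flagged low ctDNA)" else "")

  list(normalized = normalized, corrected = corrected, profile = profile,
       segments = segments, cbs = seg_cbs, alt = seg_alt, gene_z = gene_z,
       tumor_fraction = tf, log = log)
}

# Build panel + control matrix from a list of raw control count vectors.
panel_from_raw_controls <- function(windows, control_raw, lowess_fraction,
                                    sex = NA_character_) {
  corrected <- vapply(control_raw, function(raw) {
    gc_correct(median_normalize(raw), windows$gc, lowess_fraction)
  }, numeric(nrow(windows)))
  list(panel = build_control_panel(corrected, sex = sex),
       controls_corrected = corrected)
}

#' Run the full plasma copy-number pipeline
#'
#' End-to-end orchestration: obtain window counts for the sample and the
#' control cohort (from count-table files, or simulated from a reference
#' model), build the control panel, analyze the sample with
#' [analyze_sample()], and write the report bundle to `config$out_dir`:
#' `counts.tsv`, `log2.bedgraph`, `segments.seg`, `zscores.tsv`,
#' `tumor_fraction.json` and `run_log.txt` (every parameter and seed). Runs
#' are fully reproducible from the config and seed.
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created).}
#'     \item{sample}{either `list(counts = "<tsv>")` or a simulation spec
#'       `list(tumor_fraction =, events = data.frame(...), seed =)`.}
#'     \item{controls}{either `list(paths = c(...))` of count TSVs or
#'       `list(n = 20, seed =)` to simulate.}
#'     \item{model}{for simulation: arguments of [make_reference_model()].}
#'     \item{genes}{optional gene table path or data.frame.}
#'     \item{sex}{sample sex label; must match the panel's when both are set.}
#'     \item{params}{overrides of [default_params()].}
#'   }
#' @param sample_id Sample name used in outputs.
#' @return Invisibly, the [analyze_sample()] result plus `windows`, `panel`,
#'   and `out_dir`.
#' @export
run_pipeline <- function(config, sample_id = "sample") {
  if (is.character(config)) config <- read_config(config)
  p <- utils::modifyList(default_params(), config$params %||% list())
  stop_if_not(!is.null(config$out_dir), "config$out_dir is missing")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sex <- config$sex %||% NA_character_

  if (!is.null(config$model)) {
    model <- do.call(make_reference_model, config$model)
    windows <- model$windows
  } else {
    model <- NULL
  }

  # --- controls ---
  ctl <- config$controls
  stop_if_not(!is.null(ctl), "config$controls is missing")
  if (!is.null(ctl$paths)) {
    loaded <- lapply(ctl$paths, read_window_counts)
    windows <- loaded[[1]]$windows
    control_raw <- lapply(loaded, `[[`, "counts")
  } else {
    stop_if_not(!is.null(model), "simulated controls need config$model")
    n_ctl <- ctl$n %||% 20L
    ctl_seed <- ctl$seed %||% p$seed
    control_raw <- lapply(seq_len(n_ctl), function(k) {
      simulate_counts(model, NULL,
                      mean_depth = ctl$mean_depth %||% 65,
                      dispersion = ctl$dispersion %||% 0.003,
                      seed = if (is.null(ctl_seed)) NULL else ctl_seed + k)$counts
    })
  }

  # --- sample ---
  smp <- config$sample
  stop_if_not(!is.null(smp), "config$sample is missing")
  if (!is.null(smp$counts)) {
    loaded <- read_window_counts(smp$counts)
    windows <- if (is.null(windows)) loaded$windows else windows
    raw <- loaded$counts
  } else {
    stop_if_not(!is.null(model), "a simulated sample needs config$model")
    truth <- truth_profile(smp$events, smp$tumor_fraction %||% 0)
    raw <- simulate_counts(model, truth,
                           mean_depth = smp$mean_depth %||% 65,
                           dispersion = smp$dispersion %||% 0.003,
                           seed = smp$seed %||% p$seed)$counts
  }
  stop_if_not(length(raw) == nrow(windows),
              "sample and control window grids differ")

  pan <- panel_from_raw_controls(windows, control_raw, p$lowess_fraction, sex)
  if (!is.na(sex) && !is.na(pan$panel$sex %||% NA) &&
      !identical(sex, pan$panel$sex))
    stop("sample sex does not match the control panel", call. = FALSE)

  genes <- config$genes
  if (is.character(genes)) genes <- read_genes(genes)

  res <- analyze_sample(windows, raw, pan$panel, pan$controls_corrected,
                        genes = genes, params = p)

  # --- report bundle ---
  counts_tab <- data.frame(chrom = windows$chrom, start = windows$start,
                           end = windows$end, gc = windows$gc, raw = raw,
                           normalized = round(res$normalized, 6),
                           corrected = round(res$corrected, 6))
  write.table(counts_tab, file.path(out_dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bedgraph(res$profile$log2, windows, file.path(out_dir, "log2.bedgraph"))
  write_seg(res$segments, file.path(out_dir, "segments.seg"), sample_id)
  ztab <- res$segments[, c("chrom", "start", "end", "n_windows", "mean_log2",
                           "z", "significance", "basis", "call")]
  ztab$region <- sprintf("%s:%d-%d", ztab$chrom, ztab$start + 1, ztab$end)
  ztab$name <- NA_character_
  if (!is.null(res$gene_z)) {
    gz <- res$gene_z
    gtab <- data.frame(chrom = gz$chrom, start = gz$start - 1, end = gz$end,
                       n_windows = NA_integer_, mean_log2 = NA_real_,
                       z = gz$z, significance = gz$significance,
                       basis = "counts", call = NA_character_,
                       region = sprintf("%s:%d-%d", gz$chrom, gz$start, gz$end),
                       name = gz$name)
    ztab <- rbind(ztab, gtab)
  }
  ztab$z <- round(ztab$z, 4)
  ztab$mean_log2 <- round(ztab$mean_log2, 6)
  write.table(ztab, file.path(out_dir, "zscores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = sample_id, f_hat = res$tumor_fraction$f_hat,
         flagged_low_ctdna = res$tumor_fraction$flagged,
         method_note = res$tumor_fraction$method_note),
    file.path(out_dir, "tumor_fraction.json"), auto_unbox = TRUE, digits = NA
  )
  par_lines <- vapply(names(p), function(nm)
    paste0("param ", nm, " = ", paste(format(p[[nm]]), collapse = ",")), "")
  writeLines(c(paste0("sample_id = ", sample_id), par_lines, res$log),
             file.path(out_dir, "run_log.txt"))

  invisible(c(res, list(windows = windows, panel = pan$panel,
                        out_dir = out_dir)))
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    stop_if_not(requireNamespace("yaml", quietly = TRUE),
                "reading YAML configs needs the yaml package")
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$sample$events))
    cfg$sample$events <- as.data.frame(cfg$sample$events)
  cfg
}

#' Compare serial samples for emerging copy-number events
#'
#' Given z-score tables of the same regions from serially drawn samples
#' (ordered by draw date), finds regions that were not significant at the
#' baseline draw (|z| <= threshold) but became significantly overrepresented
#' later (z > threshold) — the signature of an emerging amplification such as
#' a KRAS gain under anti-EGFR therapy.
#'
#' @param z_tables List (>= 2) of data.frames that share a region identifier
#'   column (`name` if present, else `region`) and a `z` column.
#' @param baseline Index of the baseline sample (default 1).
#' @param threshold z significance threshold (default 3).
#' @return List of class `serial_comparison`: `trajectory` (region x sample z
#'   matrix as data.frame) and `emergent` (regions ranked by latest z).
#' @export
compare_serial <- function(z_tables, baseline = 1, threshold = 3) {
  stop_if_not(length(z_tables) >= 2, "need at least 2 samples")
  key <- if (!is.null(z_tables[[1]]$name) && !all(is.na(z_tables[[1]]$name)))
    "name" else "region"
  ids <- z_tables[[1]][[key]]
  for (t in z_tables) {
    stop_if_not(!is.null(t[[key]]) && !is.null(t$z),
                "z tables need region identifiers and z")
    if (!identical(t[[key]], ids))
      stop("region sets differ between samples", call. = FALSE)
  }
  zmat <- vapply(z_tables, `[[`, numeric(length(ids)), "z")
  colnames(zmat) <- names(z_tables) %||% paste0("sample_", seq_along(z_tables))
  keep <- !is.na(ids)
  traj <- data.frame(region = ids, zmat, check.names = FALSE)[keep, ]
  zb <- zmat[keep, baseline]
  zlater <- zmat[keep, -baseline, drop = FALSE]
  emergent <- abs(zb) <= threshold &
    apply(zlater, 1, function(r) any(is.finite(r) & r > threshold))
  emergent[is.na(emergent)] <- FALSE
  latest <- zmat[keep, ncol(zmat)]
  em <- traj[emergent, , drop = FALSE]
  em <- em[order(-latest[emergent]), , drop = FALSE]
  structure(list(trajectory = traj, emergent = em, baseline = baseline,
                 threshold = threshold),
            class = "serial_comparison")
}

#' @export
print.serial_comparison <- function(x, ...) {
  cat("serial comparison of", ncol(x$trajectory) - 1, "samples:",
      nrow(x$emergent), "emergent region(s)\n")
  if (nrow(x$emergent) > 0) print(utils::head(x$emergent, 10))
  invisible(x)
}
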