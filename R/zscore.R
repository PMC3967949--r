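#' Z-score of one window region against control samples
#'
#' The region statistic is the mean over the region's windows of the sample's
#' per-window values (GC-corrected normalized counts by default; log2-ratios
#' when scoring on the log2 basis). The same statistic is computed for each
#' control over the same windows, and
#' `z = (sample - mean(controls)) / sd(controls)` with the n-1 SD. Regions
#' where the control SD is zero get `z = NA` (flagged, not +/-Inf).
#'
#' @param idx Integer indices of the region's windows in the grid.
#' @param sample_values Per-window values of the sample.
#' @param control_values Matrix (windows x controls) of the controls' values.
#' @return Scalar z (NA when undefined).
#' @examples
#' ctrl <- cbind(c(90, 90), c(100, 100), c(110, 110))
#' zscore_region(1:2, c(130, 130), ctrl)  # 3
#' @export
zscore_region <- function(idx, sample_values, control_values) {
  stop_if_not(ncol(control_values) >= 3, "need at least 3 controls")
  if (length(idx) == 0) return(NA_real_)
  s <- mean(sample_values[idx])
  cs <- colMeans(control_values[idx, , drop = FALSE])
  sd_c <- sd(cs)
  if (!is.finite(sd_c) || sd_c == 0) return(NA_real_)
  (s - mean(cs)) / sd_c
}

#' Significance call from a z-score
#'
#' `z > threshold` is "over" (significantly overrepresented), `z < -threshold`
#' is "under"; the inequalities are strict, so z exactly at the threshold is
#' "neutral". Non-finite z gives NA (flagged, not called). Default threshold 3.
#'
#' @param z Numeric vector of z-scores.
#' @param threshold Positive significance threshold (default 3).
#' @return Character vector in {"over", "under", "neutral"} with NA for
#'   non-finite z.
#' @examples
#' call_significance(c(3.5, -3, -7, 2))
#' @export
call_significance <- function(z, threshold = 3) {
  stop_if_not(threshold > 0, "threshold must be > 0")
  out <- rep(NA_character_, length(z))
  ok <- is.finite(z)
  out[ok] <- ifelse(z[ok] > threshold, "over",
                    ifelse(z[ok] < -threshold, "under", "neutral"))
  out
}

# Window indices (grid space) covered by a segment row.
segment_window_idx <- function(seg_row, usable) {
  idx <- (seg_row$start_window + 1):seg_row$end_window
  idx[usable[idx]]
}

#' Segmental z-scores
#'
#' Scores every segment against the controls with [zscore_region()] and adds
#' the significance call.
#'
#' @param segments Segment data.frame (see [segmentation]).
#' @param sample_values Per-window sample values on the scoring basis.
#' @param control_values Matrix (windows x controls) on the same basis.
#' @param usable Logical mask of scorable windows.
#' @param threshold Significance threshold (default 3).
#' @param basis Label recorded in the output: "counts" (GC-corrected
#'   normalized counts, the default basis) or "log2".
#' @return The segments with `z`, `significance` and `basis` columns.
#' @export
segmental_zscores <- function(segments, sample_values, control_values,
                              usable = NULL, threshold = 3, basis = "counts") {
  usable <- usable %||% rep(TRUE, length(sample_values))
  segments$z <- vapply(seq_len(nrow(segments)), function(k) {
    zscore_region(segment_window_idx(segments[k, ], usable),
                  sample_values, control_values)
  }, 0)
  segments$significance <- call_significance(segments$z, threshold)
  segments$basis <- basis
  segments
}

#' Gene-level z-scores with the <100 kb rule
#'
#' A gene spanning at least `min_gene_length` (default 100 kb) is treated as a
#' region of its own: its overlapping windows are scored directly. Shorter
#' genes cannot be scored reliably at shallow depth (the window-level SD is too
#' large), so they inherit the z-score of the called segment containing the
#' gene midpoint, marked `derived_from = "segment"`.
#'
#' @param genes data.frame with `name`, `chrom`, `start`, `end` (1-based
#'   inclusive, as gene annotation tables are usually written).
#' @param windows Window grid data.frame.
#' @param segments Segment data.frame with a `z` column (from
#'   [segmental_zscores()]).
#' @inheritParams segmental_zscores
#' @param min_gene_length Span below which the segment z is substituted.
#' @return data.frame with one row per gene: `name`, `chrom`, `start`, `end`,
#'   `length`, `z`, `significance`, `derived_from`.
#' @export
gene_zscores <- function(genes, windows, segments, sample_values,
                         control_values, usable = NULL, threshold = 3,
                         min_gene_length = 1e5) {
  stop_if_not(all(c("name", "chrom", "start", "end") %in% names(genes)),
              "genes needs columns name, chrom, start, end")
  stop_if_not("z" %in% names(segments),
              "segments must carry z-scores (run segmental_zscores first)")
  usable <- usable %||% rep(TRUE, length(sample_values))
  rows <- lapply(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    glen <- g$end - g$start + 1
    on_chrom <- windows$chrom == g$chrom
    if (!any(on_chrom & windows$end > g$start - 1 & windows$start < g$end))
      stop("gene ", g$name, " lies outside the windowed genome", call. = FALSE)
    if (glen >= min_gene_length) {
      idx <- which(on_chrom & windows$end > g$start - 1 & windows$start < g$end &
                     usable)
      z <- zscore_region(idx, sample_values, control_values)
      derived <- "gene-region"
    } else {
      mid <- floor((g$start - 1 + g$end) / 2)
      seg <- segments[segments$chrom == g$chrom, , drop = FALSE]
      hit <- which(seg$start <= mid & seg$end > mid)
      if (length(hit) == 0)  # midpoint in a masked gap: nearest segment
        hit <- which.min(pmax(seg$start - mid, 0) + pmax(mid - seg$end + 1, 0))
      z <- seg$z[hit[1]]
      derived <- "segment"
    }
    data.frame(name = g$name, chrom = g$chrom, start = g$start, end = g$end,
               length = glen, z = z,
               significance = call_significance(z, threshold),
               derived_from = derived, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate the tumor DNA fraction from the segmented profile
#'
#' A reconstruction of the "tumor fraction from the copy-number profile"
#' estimate: the largest-span aberrant segment is assumed to be a single-copy
#' event in the tumor, so its count-scale level R satisfies `R = 1 + f/2`
#' (gain) or `R = 1 - f/2` (loss), giving `f = 2|R - 1|`, clamped to \[0, 1\].
#' R is taken from the segment's `mean_ratio` (mean per-window `2^log2`) when
#' available, which is unbiased at shallow depth, falling back to
#' `2^mean_log2`.
#'
#' A segment qualifies as aberrant when it spans at least `min_span_fraction`
#' of all usable windows and its |mean_log2| clears
#' `max(noise_floor, se_mult * window_sd / sqrt(n_windows))` — an absolute
#' floor plus a standard-error floor so genome-wide scans do not latch onto
#' noise-level segments. If nothing qualifies the estimate is 0 and flagged
#' `low_ctdna`.
#'
#' @param segments Segment data.frame.
#' @param window_sd Per-window noise SD of the log2 profile (for the SE floor);
#'   pass `estimate_window_sd` output or leave NULL to use the absolute floor
#'   only.
#' @param min_span_fraction Minimum segment span as a fraction of usable
#'   windows (default 0.01, about the smallest chromosome arm).
#' @param noise_floor Absolute floor on |mean_log2| (default 0.03, i.e. a
#'   tumor fraction of about 4%, below the method's sensitivity).
#' @param se_mult Multiplier on the segment-mean standard error (default 3.5).
#' @return List of class `tumor_fraction`: `f_hat`, `flagged` (TRUE when no
#'   qualifying segment), `segment` (the source row or NULL), `method_note`.
#' @examples
#' seg <- data.frame(chrom = "chr1", n_windows = 200,
#'                   mean_log2 = log2(1.1), mean_ratio = 1.1)
#' estimate_tumor_fraction(seg)$f_hat  # 0.2
#' @export
estimate_tumor_fraction <- function(segments, window_sd = NULL,
                                    min_span_fraction = 0.01,
                                    noise_floor = 0.03, se_mult = 3.5) {
  note <- paste("largest-span aberrant segment assumed single-copy;",
                "f = 2|R - 1| with R the count-scale segment level")
  total <- sum(segments$n_windows)
  floor_i <- noise_floor
  if (!is.null(window_sd) && window_sd > 0)
    floor_i <- pmax(noise_floor, se_mult * window_sd / sqrt(segments$n_windows))
  qual <- segments$n_windows >= min_span_fraction * total &
    abs(segments$mean_log2) > floor_i & is.finite(segments$mean_log2)
  if (!any(qual)) {
    return(structure(list(f_hat = 0, flagged = TRUE, segment = NULL,
                          method_note = paste(note, "(no qualifying segment)")),
                     class = "tumor_fraction"))
  }
  cand <- segments[qual, , drop = FALSE]
  cand <- cand[order(-cand$n_windows, -abs(cand$mean_log2)), , drop = FALSE]
  top <- cand[1, , drop = FALSE]
  r <- if ("mean_ratio" %in% names(top) && is.finite(top$mean_ratio))
    top$mean_ratio else 2^top$mean_log2
  f <- if (top$mean_log2 > 0) 2 * (r - 1) else 2 * (1 - r)
  structure(list(f_hat = min(max(f, 0), 1), flagged = FALSE, segment = top,
                 method_note = note),
            class = "tumor_fraction")
}

#' @export
print.tumor_fraction <- function(x, ...) {
  cat("tumor fraction estimate:", format(x$f_hat, digits = 3),
      if (x$flagged) "(flagged: low ctDNA)" else "", "\n")
  invisible(x)
}
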