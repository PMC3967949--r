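#' @name segmentation
#' @title Segmentation of log2-ratio profiles
#'
#' @description
#' Three segmenters share one output format: [cbs_segment()] (circular binary
#' segmentation with a permutation test), [alt_segment()] (exact penalized
#' least-squares changepoint search by optimal partitioning), and
#' [consensus_segments()] (breakpoint union of the two, with re-merging).
#' Segments are contiguous runs of usable windows; masked windows are excised
#' before segmentation and segments are reported in genomic coordinates
#' spanning the gaps.
#'
#' Each segmenter returns a data.frame with one row per segment: `chrom`,
#' `start_window`/`end_window` (0-based half-open indices into the full window
#' grid), `start`/`end` (genomic, 0-based half-open), `n_windows` (usable
#' windows in the segment), `mean_log2` (arithmetic mean of member windows'
#' log2-ratios) and `mean_ratio` (mean of per-window `2^log2`, the count-scale
#' segment level used for tumor-fraction estimation).
NULL

# Default single-chromosome pseudo-grid for plain numeric input.
default_windows <- function(n) {
  data.frame(chrom = "chr1", start = as.numeric(0:(n - 1)),
             end = as.numeric(1:n), stringsAsFactors = FALSE)
}

as_profile_input <- function(x, windows, usable) {
  if (inherits(x, "log2_profile")) {
    if (is.null(usable)) usable <- x$usable
    x <- x$log2
  }
  if (is.null(windows)) windows <- default_windows(length(x))
  if (is.null(usable)) usable <- is.finite(x)
  stop_if_not(length(x) == nrow(windows), "profile and windows lengths differ")
  stop_if_not(length(x) == length(usable), "profile and usable lengths differ")
  list(x = x, windows = windows, usable = usable & is.finite(x))
}

# Recursive CBS on one (usable) series; returns sorted cut positions in
# 1..(n-1): a cut at c separates x[1..c] from x[c+1..n].
cbs_cuts <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  cuts <- integer(0)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return()
    seg <- x[lo:hi]
    arc <- cbs_max_arc(seg, min_width)
    if (arc$i < 0) return()
    perm <- cbs_perm_count(seg, min_width, n_perm, arc$t, alpha)
    if (perm$done < n_perm) return()          # early-terminated: p >= alpha
    p <- (1 + perm$exceed) / (1 + n_perm)
    if (p >= alpha) return()
    i <- arc$i; j <- arc$j                     # arc = (i, j] within seg
    new_cuts <- integer(0)
    if (i > 0) new_cuts <- c(new_cuts, lo - 1 + i)
    if (j < m) new_cuts <- c(new_cuts, lo - 1 + j)
    cuts <<- c(cuts, new_cuts)
    bounds <- sort(unique(c(lo - 1, new_cuts, hi)))
    for (b in seq_len(length(bounds) - 1))
      recurse(bounds[b] + 1, bounds[b + 1])
  }
  recurse(1, n)
  sort(unique(cuts))
}

# Merge adjacent segments whose means differ by less than `tol`, smallest
# difference first. `cuts` as in cbs_cuts.
merge_cuts <- function(x, cuts, tol) {
  repeat {
    if (length(cuts) == 0 || tol <= 0) return(cuts)
    bounds <- c(0, cuts, length(x))
    means <- vapply(seq_len(length(bounds) - 1), function(k) {
      mean(x[(bounds[k] + 1):bounds[k + 1]])
    }, 0)
    d <- abs(diff(means))
    if (min(d) >= tol) return(cuts)
    cuts <- cuts[-which.min(d)]
  }
}

# Pooled within-segment SD given cuts.
pooled_segment_sd <- function(x, cuts) {
  bounds <- c(0, cuts, length(x))
  sse <- 0
  for (k in seq_len(length(bounds) - 1)) {
    seg <- x[(bounds[k] + 1):bounds[k + 1]]
    sse <- sse + sum((seg - mean(seg))^2)
  }
  df <- length(x) - (length(cuts) + 1)
  if (df <= 0) return(0)
  sqrt(sse / df)
}

# Exact optimal-partitioning DP: minimize sum of segment SSEs + penalty per
# changepoint, each segment >= min_width long.
op_cuts <- function(x, penalty, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(integer(0))
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  sse <- function(i, j)  # segment x[(i+1)..j], vectorized over i
    (s2[j + 1] - s2[i + 1]) - (s1[j + 1] - s1[i + 1])^2 / (j - i)
  f <- rep(Inf, n + 1)
  back <- rep(NA_integer_, n + 1)
  f[1] <- 0
  for (j in min_width:n) {
    cand <- 0:(j - min_width)
    cand <- cand[is.finite(f[cand + 1])]
    if (length(cand) == 0) next
    vals <- f[cand + 1] + sse(cand, j) + ifelse(cand == 0, 0, penalty)
    best <- which.min(vals)
    f[j + 1] <- vals[best]
    back[j + 1] <- cand[best]
  }
  cuts <- integer(0)
  j <- n
  while (!is.na(back[j + 1]) && back[j + 1] > 0) {
    j <- back[j + 1]
    cuts <- c(j, cuts)
  }
  cuts
}

# Robust per-window noise SD from first differences.
estimate_window_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) return(0)
  s <- mad(diff(x)) / sqrt(2)
  if (s == 0) s <- sd(x)
  s
}

# Build the segment data.frame for one chromosome from cuts on its usable series.
segments_from_cuts <- function(ch, x_u, g_idx, cuts, windows) {
  bounds <- c(0, cuts, length(x_u))
  rows <- lapply(seq_len(length(bounds) - 1), function(k) {
    a <- bounds[k] + 1
    b <- bounds[k + 1]
    first <- g_idx[a]
    last <- g_idx[b]
    data.frame(
      chrom = ch,
      start_window = first - 1L,   # 0-based half-open grid indices
      end_window = last,
      start = windows$start[first],
      end = windows$end[last],
      n_windows = b - a + 1L,
      mean_log2 = mean(x_u[a:b]),
      mean_ratio = mean(2^x_u[a:b]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Shared driver: apply a per-chromosome cut finder and assemble segments.
segment_with <- function(x, windows, usable, cut_fun) {
  inp <- as_profile_input(x, windows, usable)
  out <- list()
  for (ch in unique(inp$windows$chrom)) {
    g_idx <- which(inp$windows$chrom == ch & inp$usable)
    if (length(g_idx) == 0) {
      message("segmentation: no usable windows on ", ch)
      next
    }
    x_u <- inp$x[g_idx]
    cuts <- if (length(x_u) == 1) integer(0) else cut_fun(x_u)
    out[[ch]] <- segments_from_cuts(ch, x_u, g_idx, cuts, inp$windows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Circular binary segmentation
#'
#' Recursively searches each chromosome for the arc (i, j] maximizing the
#' standardized mean difference between windows inside and outside the arc,
#' accepts the split if its permutation p-value is below `alpha`, and recurses
#' into the resulting pieces. Adjacent segments whose means differ by less than
#' `undo_sd` pooled within-segment SDs are re-merged afterwards (the "undo"
#' step that removes splits too small to matter).
#'
#' @param x A `log2_profile`, or a numeric vector of per-window log2-ratios.
#' @param windows Window grid data.frame (`chrom`, `start`, `end`); when NULL a
#'   single pseudo-chromosome of unit windows is assumed.
#' @param usable Logical mask of scorable windows; defaults to finite values
#'   (or the profile's own mask).
#' @param alpha Significance level of the permutation test (default 0.01).
#' @param n_permutations Permutations per test (default 1000).
#' @param min_width Minimum windows per segment (default 2).
#' @param undo_sd Re-merge threshold in pooled-SD units (default 1).
#' @param seed Integer seed for the permutation RNG.
#' @return Segment data.frame (see [segmentation]).
#' @examples
#' x <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
#' cbs_segment(x, seed = 1)
#' @export
cbs_segment <- function(x, windows = NULL, usable = NULL, alpha = 0.01,
                        n_permutations = 1000L, min_width = 2L, undo_sd = 1,
                        seed = NULL) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stop_if_not(min_width >= 1, "min_width must be >= 1")
  with_seed(seed, segment_with(x, windows, usable, function(x_u) {
    cuts <- cbs_cuts(x_u, alpha, n_permutations, min_width)
    if (length(cuts) > 0 && undo_sd > 0)
      cuts <- merge_cuts(x_u, cuts, undo_sd * pooled_segment_sd(x_u, cuts))
    cuts
  }))
}

#' Penalized least-squares segmentation (optimal partitioning)
#'
#' Exact minimizer of segment sum-of-squared-errors plus a per-changepoint
#' penalty, found by an O(n^2) dynamic program. Serves as the second,
#' deterministic segmentation algorithm next to [cbs_segment()]; an infinite
#' penalty returns one segment per chromosome.
#'
#' @inheritParams cbs_segment
#' @param penalty Per-changepoint penalty in SSE units; default
#'   `3 * sigma^2 * log(n)` per chromosome, with `sigma` the robust per-window
#'   noise SD (median absolute first difference / sqrt(2)).
#' @return Segment data.frame (see [segmentation]).
#' @examples
#' x <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
#' alt_segment(x)
#' @export
alt_segment <- function(x, windows = NULL, usable = NULL, penalty = NULL,
                        min_width = 2L) {
  segment_with(x, windows, usable, function(x_u) {
    pen <- penalty %||% max(3 * estimate_window_sd(x_u)^2 * log(length(x_u)), 1e-12)
    if (!is.finite(pen)) return(integer(0))
    op_cuts(x_u, pen, min_width)
  })
}

#' Consensus of two segmentations
#'
#' Takes the union of both segmenters' breakpoints, recomputes segment means
#' from the profile, and re-merges adjacent consensus segments whose means
#' differ by less than `merge_tol` (smallest difference first). The union is a
#' conservative summary: every boundary either method found survives unless the
#' flanking levels are indistinguishable.
#'
#' @param seg_a,seg_b Segment data.frames from the two methods, covering the
#'   same usable windows.
#' @inheritParams cbs_segment
#' @param merge_tol Re-merge threshold on |mean difference| in log2 units
#'   (default 0.05).
#' @return Segment data.frame (see [segmentation]).
#' @export
consensus_segments <- function(seg_a, seg_b, x, windows = NULL, usable = NULL,
                               merge_tol = 0.05) {
  inp <- as_profile_input(x, windows, usable)
  cuts_of <- function(seg, ch, g_idx) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0)
      stop("segmentations do not cover the same windows (", ch, ")", call. = FALSE)
    s <- s[order(s$start_window), , drop = FALSE]
    if (sum(s$n_windows) != length(g_idx))
      stop("segmentation window coverage mismatch on ", ch, call. = FALSE)
    cumsum(s$n_windows)[-nrow(s)]
  }
  out <- list()
  for (ch in unique(inp$windows$chrom)) {
    g_idx <- which(inp$windows$chrom == ch & inp$usable)
    if (length(g_idx) == 0) next
    x_u <- inp$x[g_idx]
    cuts <- sort(unique(c(cuts_of(seg_a, ch, g_idx), cuts_of(seg_b, ch, g_idx))))
    cuts <- merge_cuts(x_u, cuts, merge_tol)
    out[[ch]] <- segments_from_cuts(ch, x_u, g_idx, cuts, inp$windows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify segments as gain / loss / balanced
#'
#' Applies the plotting thresholds: segment mean log2-ratio above
#' `gain_threshold` (default 0.2) is a gain, below `loss_threshold` (default
#' -0.2) a loss, anything else balanced.
#'
#' @param segments Segment data.frame.
#' @param gain_threshold,loss_threshold Thresholds with `gain > 0 > loss`.
#' @return The segments with a `call` column added.
#' @examples
#' classify_segments(data.frame(mean_log2 = c(0.25, 0, -0.21)))
#' @export
classify_segments <- function(segments, gain_threshold = 0.2,
                              loss_threshold = -0.2) {
  stop_if_not(gain_threshold > 0 && loss_threshold < 0,
              "need gain_threshold > 0 > loss_threshold")
  segments$call <- ifelse(segments$mean_log2 > gain_threshold, "gain",
                          ifelse(segments$mean_log2 < loss_threshold, "loss",
                                 "balanced"))
  segments
}
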