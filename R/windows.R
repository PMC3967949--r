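#' Build windows of equal mappable content
#'
#' Divides the (mask-subtracted) genome into `n_windows` windows that each
#' contain the same amount of mappable content, so that a uniformly mappable
#' diploid sample yields flat window counts. Chromosomes receive window counts
#' proportional to their total mappable weight (largest-remainder rounding);
#' windows never span chromosome boundaries. Within a chromosome, boundaries
#' are placed on the cumulative mappable-weight scale, so per-window content is
#' equal up to the weight of a single base.
#'
#' Regions such as the pseudoautosomal region (PAR) should be passed as
#' `masked_regions`; their weight is removed before division.
#'
#' @param mappability data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `weight` (mappable weight per base over the block, like a
#'   bedGraph). A pooled-control read-density track works the same way.
#' @param n_windows Total number of windows (default 50,000, the genome-wide
#'   grid used at ~0.1-0.2x coverage).
#' @param masked_regions Optional data.frame `chrom`, `start`, `end` of regions
#'   to exclude (e.g. the PAR).
#' @param gc Optional data.frame `chrom`, `start`, `end`, `gc` giving a GC
#'   track; per-window GC is its length-weighted mean over the window.
#' @return data.frame of class `genome_windows` with columns `chrom`, `start`,
#'   `end`, `mappable` (content per window), `gc` (NA when no track given).
#' @examples
#' mp <- data.frame(chrom = "chr1", start = 0, end = 1000, weight = 1)
#' build_equal_mappability_windows(mp, n_windows = 10)
#' @export
build_equal_mappability_windows <- function(mappability, n_windows = 50000L,
                                            masked_regions = NULL, gc = NULL) {
  stop_if_not(n_windows >= 1, "n_windows must be >= 1")
  need <- c("chrom", "start", "end", "weight")
  stop_if_not(all(need %in% names(mappability)),
              "mappability needs columns chrom, start, end, weight")
  mp <- mappability[mappability$end > mappability$start &
                      mappability$weight > 0, , drop = FALSE]
  if (!is.null(masked_regions))
    mp <- subtract_regions(mp, masked_regions)
  mp <- mp[order(match(mp$chrom, unique(mappability$chrom)), mp$start), , drop = FALSE]
  mp$w_total <- (mp$end - mp$start) * mp$weight
  chroms <- unique(mp$chrom)
  w_chrom <- vapply(chroms, function(ch) sum(mp$w_total[mp$chrom == ch]), 0)
  total <- sum(w_chrom)
  if (total < n_windows)
    stop("total mappable content (", round(total, 2),
         ") is below one unit per window", call. = FALSE)
  alloc <- largest_remainder(n_windows * w_chrom / total, n_windows)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    m <- alloc[k]
    if (m == 0) next
    blocks <- mp[mp$chrom == ch, , drop = FALSE]
    cum <- c(0, cumsum(blocks$w_total))
    targets <- w_chrom[k] * seq_len(m - 1) / m
    cuts <- vapply(targets, function(tg) {
      b <- findInterval(tg, cum, left.open = TRUE)   # block index reaching tg
      b <- min(max(b, 1), nrow(blocks))
      pos <- blocks$start[b] + (tg - cum[b]) / blocks$weight[b]
      round(pos)
    }, 0)
    starts <- c(blocks$start[1], cuts)
    ends <- c(cuts, blocks$end[nrow(blocks)])
    keep <- ends > starts
    win <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                      stringsAsFactors = FALSE)
    win$mappable <- vapply(seq_len(nrow(win)), function(i) {
      interval_weight(blocks, win$start[i], win$end[i])
    }, 0)
    out[[k]] <- win
  }
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  win$gc <- if (is.null(gc)) NA_real_ else per_window_gc(win, gc)
  class(win) <- c("genome_windows", "data.frame")
  win
}

# Subtract masked intervals from weight blocks (per chromosome).
subtract_regions <- function(blocks, masks) {
  pieces <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, , drop = FALSE]
    mk <- masks[masks$chrom == b$chrom & masks$end > b$start &
                  masks$start < b$end, , drop = FALSE]
    if (nrow(mk) == 0) return(b)
    mk <- mk[order(mk$start), , drop = FALSE]
    starts <- c(b$start, pmin(pmax(mk$end, b$start), b$end))
    ends <- c(pmin(pmax(mk$start, b$start), b$end), b$end)
    keep <- ends > starts
    if (!any(keep)) return(NULL)
    data.frame(chrom = b$chrom, start = starts[keep], end = ends[keep],
               weight = b$weight, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
}

# Largest-remainder rounding of non-negative shares to integers summing to n.
largest_remainder <- function(shares, n) {
  fl <- floor(shares)
  rem <- n - sum(fl)
  if (rem > 0) {
    order_by_frac <- order(shares - fl, decreasing = TRUE)
    fl[order_by_frac[seq_len(rem)]] <- fl[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# Total mappable weight of blocks overlapping [start, end).
interval_weight <- function(blocks, start, end) {
  ov_start <- pmax(blocks$start, start)
  ov_end <- pmin(blocks$end, end)
  sum(pmax(ov_end - ov_start, 0) * blocks$weight)
}

per_window_gc <- function(win, gc_track) {
  vapply(seq_len(nrow(win)), function(i) {
    g <- gc_track[gc_track$chrom == win$chrom[i] &
                    gc_track$end > win$start[i] &
                    gc_track$start < win$end[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_real_)
    len <- pmin(g$end, win$end[i]) - pmax(g$start, win$start[i])
    sum(g$gc * len) / sum(len)
  }, 0)
}

#' Count read start positions per window
#'
#' Assigns each read to the unique window with `start <= pos < end` (half-open;
#' a read at a window's `end` belongs to the next window). Reads on unknown
#' chromosomes or outside the windowed extent are dropped with a warning-level
#' log message; counted + dropped always equals the input.
#'
#' @param reads data.frame with `chrom` and `pos` (0-based read start).
#' @param windows A `genome_windows` data.frame (or any data.frame with
#'   `chrom`, `start`, `end` sorted within chromosome).
#' @return List of class `read_counts`: `raw` (integer per-window counts),
#'   `n_counted`, `n_dropped`.
#' @examples
#' mp <- data.frame(chrom = "chr1", start = 0, end = 100, weight = 1)
#' w <- build_equal_mappability_windows(mp, n_windows = 4)
#' count_reads(data.frame(chrom = "chr1", pos = c(0, 25, 25, 99)), w)$raw
#' @export
count_reads <- function(reads, windows) {
  stop_if_not(all(c("chrom", "pos") %in% names(reads)),
              "reads needs columns chrom, pos")
  raw <- integer(nrow(windows))
  dropped <- 0L
  unknown <- setdiff(unique(reads$chrom), unique(windows$chrom))
  if (length(unknown) > 0) {
    n_un <- sum(reads$chrom %in% unknown)
    warning("dropping ", n_un, " reads on unknown chromosome(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    dropped <- dropped + n_un
    reads <- reads[!reads$chrom %in% unknown, , drop = FALSE]
  }
  for (ch in unique(reads$chrom)) {
    widx <- which(windows$chrom == ch)
    pos <- reads$pos[reads$chrom == ch]
    i <- findInterval(pos, windows$start[widx])
    ok <- i >= 1 & pos < windows$end[widx][pmax(i, 1)]
    dropped <- dropped + sum(!ok)
    tab <- tabulate(i[ok], nbins = length(widx))
    raw[widx] <- raw[widx] + tab
  }
  structure(list(raw = raw, n_counted = sum(raw), n_dropped = dropped),
            class = "read_counts")
}

#' Median-normalize raw window counts
#'
#' Divides each window's raw count by the sample median so that samples of
#' different depth become comparable; the median of the result is 1.
#'
#' @param raw Non-negative numeric vector of raw window counts.
#' @return Numeric vector of normalized counts.
#' @examples
#' median_normalize(c(2, 4, 6))
#' @export
median_normalize <- function(raw) {
  stop_if_not(any(raw > 0), "all counts are zero")
  med <- median(raw)
  if (med == 0)
    stop("median read count is zero; sample too shallow to normalize",
         call. = FALSE)
  raw / med
}
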