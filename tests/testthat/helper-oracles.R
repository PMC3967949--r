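# Brute-force changepoint oracles, independent of the package's segmenters.

# SSE of a segmentation of x given sorted cuts (cut c separates x[1..c] from
# x[(c+1)..n]).
oracle_sse <- function(x, cuts) {
  bounds <- c(0, cuts, length(x))
  s <- 0
  for (k in seq_len(length(bounds) - 1)) {
    seg <- x[(bounds[k] + 1):bounds[k + 1]]
    s <- s + sum((seg - mean(seg))^2)
  }
  s
}

# All cut sets of size k with every segment >= min_width windows.
oracle_cut_sets <- function(n, k, min_width = 2) {
  if (k == 0) return(list(integer(0)))
  pos <- seq(min_width, n - min_width)
  if (length(pos) < k) return(list())
  sets <- utils::combn(pos, k, simplify = FALSE)
  Filter(function(cuts) all(diff(c(0, cuts, n)) >= min_width), sets)
}

# Exhaustive best cuts for exactly k changepoints.
oracle_best_cuts <- function(x, k, min_width = 2) {
  sets <- oracle_cut_sets(length(x), k, min_width)
  sse <- vapply(sets, function(cuts) oracle_sse(x, cuts), 0)
  sets[[which.min(sse)]]
}

# Exhaustive penalized optimum over 0..max_k changepoints.
oracle_penalized_cuts <- function(x, penalty, min_width = 2, max_k = 3) {
  best <- integer(0)
  best_cost <- oracle_sse(x, integer(0))
  for (k in seq_len(max_k)) {
    for (cuts in oracle_cut_sets(length(x), k, min_width)) {
      cost <- oracle_sse(x, cuts) + k * penalty
      if (cost < best_cost - 1e-10) {
        best_cost <- cost
        best <- cuts
      }
    }
  }
  best
}

# Cut positions (within-chromosome, usable-window space) implied by a segment
# data.frame for one chromosome.
segment_cuts <- function(segments, chrom = NULL) {
  s <- if (is.null(chrom)) segments else
    segments[segments$chrom == chrom, , drop = FALSE]
  s <- s[order(s$start_window), , drop = FALSE]
  head(cumsum(s$n_windows), -1)
}

# A small multi-chromosome grid for segmentation tests.
toy_windows <- function(n_per_chrom, chroms = paste0("chr", seq_along(n_per_chrom))) {
  do.call(rbind, lapply(seq_along(n_per_chrom), function(k) {
    n <- n_per_chrom[k]
    data.frame(chrom = chroms[k], start = as.numeric(0:(n - 1)) * 1000,
               end = as.numeric(1:n) * 1000, stringsAsFactors = FALSE)
  }))
}
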