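#' Write segments in SEG format
#'
#' SEG is 1-based inclusive: `loc.start = start + 1`, `loc.end = end` for the
#' package's internal 0-based half-open coordinates.
#'
#' @param segments Segment data.frame.
#' @param path Output path.
#' @param sample_id ID written in the first column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample_id = "sample") {
  out <- data.frame(
    ID = sample_id,
    chrom = segments$chrom,
    loc.start = segments$start + 1,
    loc.end = segments$end,
    num.mark = segments$n_windows,
    seg.mean = round(segments$mean_log2, 6)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-window signal as bedGraph
#'
#' 0-based half-open records; windows with NA signal are skipped.
#'
#' @param values Per-window numeric signal (e.g. log2-ratios).
#' @param windows Window grid data.frame.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, windows, path, name = "log2_ratio") {
  keep <- is.finite(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  write.table(
    data.frame(windows$chrom[keep], windows$start[keep], windows$end[keep],
               round(values[keep], 6)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write and read a control panel as TSV
#'
#' Columns `chrom`, `start`, `end`, `mean`, `sd`, `usable`; the control count
#' travels in a `# n_controls=` header comment.
#'
#' @param panel A [build_control_panel()] object.
#' @param windows Window grid the panel lives on.
#' @param path File path.
#' @return `path` (write) or a `control_panel` (read).
#' @export
write_panel <- function(panel, windows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_controls=%d sex=%s", panel$n_controls,
                     panel$sex %||% NA), con)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, mean = panel$mean, sd = panel$sd,
                    usable = panel$usable)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  header <- readLines(path, n = 1)
  n <- as.integer(sub(".*n_controls=(\\d+).*", "\\1", header))
  sex <- sub(".*sex=(\\S+).*", "\\1", header)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(n_controls = n, mean = tab$mean, sd = tab$sd,
                 usable = as.logical(tab$usable), sex = sex),
            class = "control_panel")
}

#' Read a window-count table
#'
#' Expects the TSV written by [write_window_counts()] (`chrom`, `start`, `end`,
#' `gc`, `count`); extra columns are kept on the window grid.
#'
#' @param path TSV path.
#' @return List with `windows` (data.frame) and `counts` (integer vector).
#' @export
read_window_counts <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stop_if_not(all(c("chrom", "start", "end", "count") %in% names(tab)),
              "count table needs columns chrom, start, end, count")
  counts <- as.integer(tab$count)
  tab$count <- NULL
  list(windows = tab, counts = counts)
}

#' Read a gene annotation table
#'
#' Accepts a TSV with `name`, `chrom`, `start`, `end` (1-based inclusive, the
#' usual gene-table convention) or a BED4 file (0-based half-open, converted).
#'
#' @param path File path; `.bed` files are treated as BED4.
#' @return data.frame with `name`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_genes <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)[, 1:4]
    names(tab) <- c("chrom", "start", "end", "name")
    tab$start <- tab$start + 1  # BED 0-based half-open -> 1-based inclusive
    return(tab[, c("name", "chrom", "start", "end")])
  }
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stop_if_not(all(c("name", "chrom", "start", "end") %in% names(tab)),
              "gene table needs columns name, chrom, start, end")
  tab
}

#' Write the window grid as BED4
#'
#' @param windows Window grid data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  out <- data.frame(windows$chrom, windows$start, windows$end,
                    seq_len(nrow(windows)) - 1)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
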