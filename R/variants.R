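#' Filter pileup reads on mapping quality
#'
#' Removes reads with `mapq < mapq_min` (strict: MAPQ exactly at the cutoff is
#' retained). Default cutoff 15, the standard alignment filter for targeted
#' deep sequencing.
#'
#' @param pileup data.frame with at least `allele`, `mapq`, `baseq`, `masked`.
#' @param mapq_min Minimum retained mapping quality (default 15).
#' @return The pileup with low-MAPQ reads removed.
#' @examples
#' p <- data.frame(allele = "ref", mapq = c(14, 15), baseq = 30, masked = FALSE)
#' filter_reads(p)$mapq
#' @export
filter_reads <- function(pileup, mapq_min = 15) {
  stop_if_not(mapq_min >= 0, "mapq_min must be >= 0")
  pileup[pileup$mapq >= mapq_min, , drop = FALSE]
}

#' Mask pileup bases on base quality
#'
#' Sets `masked = TRUE` for bases with Phred score below `baseq_min` (strict:
#' a base exactly at the cutoff stays unmasked). Masked bases are excluded from
#' both numerator and denominator of the variant allele fraction. Default
#' cutoff Phred 20.
#'
#' @inheritParams filter_reads
#' @param baseq_min Minimum unmasked base quality (default 20).
#' @return The pileup with the `masked` column updated.
#' @examples
#' p <- data.frame(allele = "ref", mapq = 60, baseq = c(19, 20), masked = FALSE)
#' mask_bases(p)$masked
#' @export
mask_bases <- function(pileup, baseq_min = 20) {
  stop_if_not(baseq_min >= 0, "baseq_min must be >= 0")
  pileup$masked <- pileup$masked | pileup$baseq < baseq_min
  pileup
}

#' Call a sequence variant from a filtered pileup
#'
#' Computes the variant allele fraction over usable (unmasked) reads,
#' `vaf = alt / depth_used`, counting non-ref, non-alt ("other") alleles in the
#' denominator. Allelic fractions below `vaf_threshold` (default 1%) are
#' treated as sequencing error (`below_threshold`); a fraction exactly at the
#' threshold is reliable and called. Calls also require
#' `depth_used >= min_depth`.
#'
#' @param pileup data.frame with `allele` ("ref"/"alt"/"other"), `masked`.
#' @param vaf_threshold Minimum reliable allele fraction, in (0, 1)
#'   (default 0.01).
#' @param min_depth Minimum usable depth for any call (default 500, a
#'   conservative floor for targeted deep sequencing).
#' @return List of class `mutation_call`: `vaf`, `depth_used`, `alt_count`,
#'   `status` in {"called", "below_threshold", "insufficient_depth"}.
#' @examples
#' p <- simulate_pileup(0.02, 10000, base_error_rate = 0, seed = 1)
#' call_mutation(p)$status
#' @export
call_mutation <- function(pileup, vaf_threshold = 0.01, min_depth = 500) {
  stop_if_not(vaf_threshold > 0 && vaf_threshold < 1,
              "vaf_threshold must be in (0, 1)")
  use <- pileup[!pileup$masked, , drop = FALSE]
  depth <- nrow(use)
  alt <- sum(use$allele == "alt")
  vaf <- if (depth > 0) alt / depth else NA_real_
  status <- if (depth == 0 || depth < min_depth) "insufficient_depth"
  else if (vaf >= vaf_threshold) "called"
  else "below_threshold"
  structure(list(vaf = vaf, depth_used = depth, alt_count = alt,
                 status = status),
            class = "mutation_call")
}

#' @export
print.mutation_call <- function(x, ...) {
  cat("mutation call:", x$status, "- VAF",
      if (is.na(x$vaf)) "NA" else format(x$vaf, digits = 3),
      "over", x$depth_used, "usable reads\n")
  invisible(x)
}
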