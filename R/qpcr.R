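#' Relative quantity by the comparative CT method
#'
#' Comparative-CT (delta-delta CT) relative quantitation for duplex qPCR
#' copy-number assays: `dCT_sample = CT_target_sample - CT_reference_sample`,
#' `dCT_cal = CT_target_calibrator - CT_reference_calibrator`,
#' `ddCT = dCT_sample - dCT_cal`, `RQ = 2^(-ddCT)`. The reference assay (for
#' example hTERT) and the normal-DNA calibrator terms are explicit arguments.
#' All arguments are vectorized.
#'
#' @param ct_target_sample,ct_reference_sample CT of target/reference assay in
#'   the sample.
#' @param ct_target_calibrator,ct_reference_calibrator CT of target/reference
#'   assay in the calibrator (normal DNA).
#' @return Positive relative quantity; 1 means the sample carries the
#'   calibrator's relative copy number.
#' @examples
#' relative_quantity(24, 25, 25, 25)  # ddCT = -1 -> RQ = 2
#' @export
relative_quantity <- function(ct_target_sample, ct_reference_sample,
                              ct_target_calibrator, ct_reference_calibrator) {
  cts <- cbind(ct_target_sample, ct_reference_sample,
               ct_target_calibrator, ct_reference_calibrator)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("all CT values must be finite and > 0", call. = FALSE)
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Squared Pearson correlation between two platforms
#'
#' Concordance statistic for cross-platform validation (for example qPCR
#' relative copy numbers against sequencing log2-ratios or z-scores): the
#' squared Pearson correlation coefficient. Zero variance in either vector
#' leaves r^2 undefined (NA with a warning) rather than an arbitrary value.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return r^2 in \[0, 1\], or NA when undefined.
#' @examples
#' concordance_r2(1:5, 2 * (1:5) + 1)  # 1
#' @export
concordance_r2 <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y lengths differ")
  stop_if_not(length(x) >= 3, "need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; r^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)^2
}
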