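#' GC-correct normalized window counts with LOWESS
#'
#' Fits a locally weighted regression of normalized counts on window GC
#' fraction and divides each count by the fitted curve (multiplicative
#' correction, so counts stay non-negative and scale noise is respected). The
#' result is rescaled to preserve the input mean exactly, making the correction
#' dosage-preserving. The fit is floored at 1e-3 of the global mean so
#' near-zero fitted values cannot blow counts up.
#'
#' @param x Normalized counts (one per window).
#' @param gc Window GC fractions, same length.
#' @param lowess_fraction LOWESS smoother span in (0, 1]; default 0.3 with one
#'   robustifying iteration.
#' @return Numeric vector of GC-corrected counts.
#' @examples
#' gc <- runif(500, 0.35, 0.65)
#' x <- (1 - 2 * (gc - 0.5)^2) * rpois(500, 100) / 100
#' cor(gc_correct(x, gc), gc)^2 < cor(x, gc)^2
#' @export
gc_correct <- function(x, gc, lowess_fraction = 0.3) {
  stop_if_not(length(x) == length(gc), "x and gc lengths differ")
  stop_if_not(lowess_fraction > 0 && lowess_fraction <= 1,
              "lowess_fraction must be in (0, 1]")
  if (sd(gc) == 0) {
    warning("all GC values identical; returning input unchanged", call. = FALSE)
    return(x)
  }
  gm <- mean(x)
  if (gm == 0) return(x)
  fit <- lowess(gc, x, f = lowess_fraction, iter = 1)
  m <- approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
  m <- pmax(m, 1e-3 * gm)
  corrected <- x * gm / m
  corrected * gm / mean(corrected)
}

#' Build a control panel from GC-corrected control samples
#'
#' Summarizes >= 3 non-cancer plasma controls (on the same window grid) as the
#' per-window mean and sample standard deviation (n-1 denominator) of their
#' GC-corrected normalized counts. Windows with zero SD are flagged unusable:
#' the z-score denominator would be undefined there.
#'
#' @param controls A numeric matrix (windows x samples) or a list of per-window
#'   numeric vectors.
#' @param sex Optional sex label of the control cohort ("M"/"F"); panels should
#'   be sex-matched to the sample being scored.
#' @return Object of class `control_panel`: list with `n_controls`, `mean`,
#'   `sd`, `usable` (logical), `sex`.
#' @examples
#' p <- build_control_panel(cbind(c(0.9, 1), c(1, 1), c(1.1, 1)))
#' p$mean; p$usable
#' @export
build_control_panel <- function(controls, sex = NA_character_) {
  if (is.list(controls) && !is.data.frame(controls))
    controls <- do.call(cbind, controls)
  controls <- as.matrix(controls)
  n <- ncol(controls)
  stop_if_not(n >= 3, "need at least 3 controls")
  mu <- rowMeans(controls)
  s <- sqrt(rowSums((controls - mu)^2) / (n - 1))
  structure(
    list(n_controls = n, mean = mu, sd = s,
         usable = is.finite(s) & s > 0 & is.finite(mu), sex = sex),
    class = "control_panel"
  )
}

#' @export
print.control_panel <- function(x, ...) {
  cat("control_panel:", x$n_controls, "controls,", length(x$mean), "windows,",
      sum(!x$usable), "unusable\n")
  invisible(x)
}

#' Per-window log2-ratios of a sample against the control panel
#'
#' `log2((corrected + pseudocount) / (panel mean + pseudocount))`, computed on
#' usable panel windows; unusable windows propagate as NA with
#' `usable = FALSE`. By default the profile is recentred so its genome-wide
#' median is zero — the usual copy-number convention that anchors the balanced
#' state at log2-ratio 0 regardless of small normalization offsets.
#'
#' @param corrected GC-corrected normalized counts of the sample.
#' @param panel A [build_control_panel()] object on the same grid.
#' @param pseudocount Stabilizer for near-zero windows; default
#'   `1e-3 * mean(panel mean)`, i.e. about 1/(10x a typical raw window depth)
#'   on the normalized scale.
#' @param center If TRUE (default), subtract the median of the usable
#'   log2-ratios.
#' @return Object of class `log2_profile`: list with `log2` (NA on unusable
#'   windows) and `usable`.
#' @examples
#' panel <- build_control_panel(matrix(1 + rnorm(300, sd = 0.05), 100, 3))
#' prof <- log2_ratios(panel$mean, panel, center = FALSE)
#' all(abs(prof$log2) < 1e-12)
#' @export
log2_ratios <- function(corrected, panel, pseudocount = NULL, center = TRUE) {
  stop_if_not(inherits(panel, "control_panel"), "panel must be a control_panel")
  stop_if_not(length(corrected) == length(panel$mean),
              "sample and panel are on different grids")
  pc <- pseudocount %||% (1e-3 * mean(panel$mean))
  l2 <- log2((corrected + pc) / (panel$mean + pc))
  l2[!panel$usable] <- NA_real_
  if (center) l2 <- l2 - median(l2[panel$usable])
  structure(list(log2 = l2, usable = panel$usable & is.finite(l2)),
            class = "log2_profile")
}
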