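# A small shared cohort for pipeline-level tests: 5 chromosomes x 80 windows,
# 6 controls at the study depth. Built once per test run.
small_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    model <- make_reference_model(5, 80, seed = 42)
    control_raw <- lapply(1:6, function(k)
      simulate_counts(model, NULL, mean_depth = 65, seed = 4200 + k)$counts)
    corrected <- vapply(control_raw, function(raw)
      gc_correct(median_normalize(raw), model$windows$gc),
      numeric(nrow(model$windows)))
    cache <<- list(model = model, windows = model$windows,
                   panel = build_control_panel(corrected),
                   controls_corrected = corrected)
    cache
  }
})

# Gene fixture on the small cohort: one sub-100 kb gene inside the canonical
# event region of chr5, one long gene elsewhere.
small_genes <- function(model) {
  ws <- model$window_size
  data.frame(
    name = c("KRAS", "LONG"),
    chrom = c("chr5", "chr2"),
    start = c(35 * ws + 5001, 20 * ws + 1),
    end = c(35 * ws + 5000 + 45674, 20 * ws + 200000),
    stringsAsFactors = FALSE
  )
}
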