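Package: plasmaCNA
Title: Copy-Number Analysis of Plasma DNA from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide copy-number profiling of cell-free plasma DNA
    sequenced at shallow depth (about 0.1-0.2x). Reads or per-window read-count
    tables are binned into equal-mappability windows, median-normalized,
    GC-corrected with LOWESS, and expressed as log2-ratios against a panel of
    non-cancer control plasma samples. Profiles are segmented with a from-scratch
    circular binary segmentation implementation plus a penalized changepoint
    method and a breakpoint-union consensus; segments and therapy-relevant gene
    regions (for example KRAS, MET, ERBB2, EGFR) are scored as z-scores against
    the control panel and the tumor DNA fraction is estimated. Also includes the
    mapping/base-quality filters and variant-allele-fraction thresholding used in
    targeted deep sequencing of resistance mutations, comparative-CT (delta-delta
    CT) arithmetic for qPCR copy-number validation, a negative-binomial synthetic
    cfDNA data generator for testing, and an end-to-end pipeline with serial
    sample comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
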