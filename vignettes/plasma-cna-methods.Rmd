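---
title: "Copy-number analysis of plasma DNA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of plasma DNA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cell-free DNA (cfDNA) in plasma carries a tumor-derived component (ctDNA)
whose abundance tracks the tumor's genome. Sequencing plasma DNA at very
shallow depth (~0.1–0.2x, single-end) and counting reads in genomic bins
yields a genome-wide copy-number profile of the tumor without a biopsy. The
difficulty is that the signal is a mixture: at tumor fraction $f$, a region
present at $CN$ copies in the tumor (diploid background) changes expected
coverage only by the factor

$$ R(CN, f) = \frac{2(1-f) + CN \cdot f}{2} = 1 + \frac{f\,(CN-2)}{2}. $$

A single-copy arm gain at $f = 0.1$ is a 5% coverage change, far below the
per-bin noise, so detection rests on averaging over many bins and on
comparing against a panel of non-cancer control plasma samples. plasmaCNA
implements this pipeline end to end, together with the mutation-calling
filters used for targeted deep sequencing of resistance genes and the
comparative-CT arithmetic used for qPCR validation of copy-number calls.

## Pipeline model

1. **Windows.** The genome (with artifact regions such as the
   pseudoautosomal region masked) is divided into windows of *equal mappable
   content* — 50,000 genome-wide by default — so that a uniform diploid
   sample gives flat counts. Chromosomes are allocated windows proportionally
   to their mappable weight (largest-remainder rounding); boundaries are
   placed on the cumulative-weight scale, making per-window content equal up
   to one base's weight. Reads are assigned by start position, half-open.
2. **Median normalization.** Counts are divided by the sample median,
   removing sequencing depth.
3. **GC correction.** A LOWESS fit of normalized counts on window GC
   (span 0.3, one robustifying iteration) estimates the sample-specific GC
   bias; counts are divided by the fit and rescaled to preserve the mean.
   The correction is multiplicative because count noise scales with the
   mean, and it keeps counts non-negative. The fitted curve is floored at
   $10^{-3}$ of the global mean so near-empty windows cannot explode.
4. **Log2-ratios.** $\log_2((x_w + c) / (\bar{m}_w + c))$ against the
   per-window mean $\bar{m}_w$ of ≥3 GC-corrected controls, with a small
   pseudocount $c$ (default $10^{-3}$ of the panel mean, i.e. about
   1/(10× a typical raw window depth)). Profiles are recentred so the
   genome-wide median is zero — the usual convention that anchors the
   balanced state at 0; without it, the small negative offset that
   $E[\log X] < \log E[X]$ induces at ~65 reads/window (~0.013 log2 units)
   would shift every segment.
5. **Segmentation.** Circular binary segmentation (CBS): recursively find
   the arc $(i, j]$ maximizing the standardized in/out mean difference,
   accept if a within-chromosome permutation p-value is below $\alpha = 0.01$
   (1000 permutations), recurse; re-merge adjacent segments closer than one
   pooled SD ("undo"). A second, deterministic segmenter — exact penalized
   least-squares changepoint search by optimal partitioning, penalty
   $3\hat\sigma^2\log n$ per changepoint — runs alongside, and the consensus
   is the breakpoint union with re-merging of segments whose means differ by
   < 0.05. The union is conservative: a boundary found by either method
   survives unless the flanking levels are indistinguishable. Segment means
   above +0.2 / below −0.2 are drawn as gain / loss.
6. **Z-scores.** For each segment (and gene region) the statistic is the
   mean of the sample's GC-corrected normalized counts over the region's
   windows; the same statistic over the same windows is computed for every
   control, and $z = (s - \bar{s}_{ctl}) / \mathrm{sd}_{ctl}$ (n−1 SD).
   $|z| > 3$ (strict) marks significant over-/under-representation. Genes
   shorter than 100 kb cannot be scored reliably at this depth (the
   window-level SD is too large), so they inherit the z of the segment
   containing the gene midpoint; longer genes (e.g. MET, EGFR) are scored
   directly on their windows. The midpoint rule makes assignment
   deterministic for genes straddling a boundary.
7. **Tumor fraction.** The largest-span aberrant segment is assumed to be a
   single-copy event, so its count-scale level $R$ gives
   $\hat f = 2\,|R - 1|$, clamped to $[0, 1]$.

```{r example}
library(plasmaCNA)
model <- make_reference_model(seed = 1)          # 22 x 230-window fixture
truth <- truth_profile(data.frame(chrom = "chr12", start_window = 100,
                                  end_window = 130, copy_number = 10), 0.1)
cohort <- study_cohort(seed = 1)                 # 20-control panel
raw <- simulate_counts(model, truth, seed = 99)$counts
res <- analyze_sample(cohort$windows, raw, cohort$panel,
                      cohort$controls_corrected,
                      genes = study_genes(model))
res$segments[res$segments$chrom == "chr12", ]
res$gene_z
```

## Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `n_windows` | 50,000 | genome-wide bins at ~0.1–0.2x; ~65 reads/window at 0.16x |
| `lowess_fraction` | 0.3 | GC smoother span; wide enough to be stable, narrow enough for curvature |
| `alpha`, `n_permutations` | 0.01, 1000 | CBS split test; permutation granularity floor is 1/1001 |
| `min_width` | 2 windows | smallest reportable segment |
| `undo_sd` | 1 pooled SD | removes splits too small to matter |
| `merge_tol` | 0.05 log2 | consensus re-merge; below arm-level signal at f ≈ 0.07 |
| `gain/loss thresholds` | ±0.2 | plotting/call thresholds |
| `z threshold` | ±3 (strict) | significance rule |
| `min_gene_length` | 100 kb | below this, gene z is segment-derived |
| MAPQ / baseQ / VAF | 15 / 20 / 1% | deep-sequencing filters (strict boundaries: 15 kept, 20 unmasked, 1% called) |
| `min_depth` | 500 | depth floor for a mutation call; targeted panels run far deeper |

Tumor-fraction qualification: a segment must span ≥1% of usable windows
(`min_span_fraction`; about the smallest chromosome arm — no arm reaches 5%
of the genome) and clear
$\max(0.03,\ 3.5\,\hat\sigma_w/\sqrt{n_{windows}})$ in $|\overline{\log_2}|$.
The absolute floor 0.03 corresponds to $f \approx 0.04$, below the method's
sensitivity; the standard-error floor stops a genome-wide scan from latching
onto chance-level whole-chromosome means (22 chromosomes offer 22 chances
per sample). $\hat f$ uses the segment's count-scale mean ratio
(`mean_ratio`, the mean of per-window $2^{\log_2}$) rather than
$2^{\overline{\log_2}}$: the arithmetic mean of window-level log2-ratios is
biased low by $\mathrm{Var}/(2\ln 2) \approx 0.013$ at ~65 reads/window,
which alone would cost ~0.02 on $\hat f$; the ratio-scale mean is unbiased.

## The synthetic generator

`make_reference_model()` + `simulate_counts()` emulate exactly the
statistical structure the analysis assumes:

- a window grid with smooth (AR(1)) GC in [0.3, 0.7] and near-unit
  mappability weights;
- negative-binomial counts, `variance = mu + dispersion * mu^2`
  (dispersion 0 = Poisson). Default dispersion 0.003 gives variance
  ≈ 1.2× Poisson at 65 reads/window, typical of GC-corrected shallow-WGS
  bins;
- a smooth unimodal quadratic GC bias with unit mean — the simplest bias
  the LOWESS stage must remove;
- tumor signal as the mixture factor $R(CN, f)$ applied to event windows.

Defaults are the study conditions: 22 autosomes × 230 windows (a 1/10-scale
stand-in for the 50,000-window grid that keeps a full analysis under a
second), 65 reads/window (the per-window depth of a 0.16x genome in
50,000-window space), and a 20-sample control panel (a cohort size the
method's sources leave unstated; 20 is typical of reference panels built for
this purpose). Fragment-length structure is *not* simulated: the pipeline
consumes window counts and fragment size never enters the computation.

What the generator does **not** emulate — and hence what green tests do not
establish about real plasma: mappability and replication-timing artifacts
beyond GC, germline CNVs in controls, subclonal mixtures of more than one
tumor clone, and batch effects between sample and panel. On real data these
raise the effective noise floor and make a matched, same-sex,
same-protocol panel essential.

## Numerical and design notes

- **Degenerate inputs.** All-identical GC returns counts unchanged with a
  warning; zero-SD panel windows are masked and propagate as unusable;
  zero-SD control statistics flag the region's z as undefined (NA, never
  ±Inf); a zero median raises an error (sample too shallow). Arc-statistic
  ties break toward the smallest (i, then j).
- **Masked windows** are excised before segmentation; segments are reported
  in genomic coordinates spanning the gaps, and coverage of usable windows
  is conserved (a tested invariant).
- **Coordinates.** 0-based half-open internally and in BED/bedGraph output;
  SEG output is 1-based inclusive; gene tables are 1-based inclusive as
  annotation tables usually are.
- **Z-score basis.** Counts basis (GC-corrected normalized counts) is the
  default; a log2-ratio basis gives the same signs and significance on
  clear events (a tested property) and is available by passing log2 values
  to the same functions.
- **Serial comparison** calls a region *emergent* when the baseline draw has
  $|z| \le 3$ and a later draw has $z > 3$ on the same region definition —
  the signature of an amplification (e.g. KRAS) appearing under therapy.

## Known limitations

- **Permutation granularity.** The CBS p-value can never drop below
  ~$n/\binom{n}{k}$ for a k-window segment, so on short series segments
  under ~7 windows are undetectable at $\alpha = 0.01$ *regardless of
  effect size*, and each accepted split spawns further size-$\alpha$ tests
  (≈2% spurious-split chance per profile). The oracle-equivalence tests
  therefore use segments of ≥7–8 windows and allow the nominal
  $\alpha$-level count slack; location agreement with exhaustive search is
  exact whenever the count is right.
- **Panel-size tails.** With a 20-control panel the null z is
  Student-t(19)-like (scaled by $\sqrt{1 + 1/20}$), so $P(|z|>3) \approx
  0.9\%$, about 3× the Gaussian 0.27%; shared-panel luck also correlates
  exceedances across samples scored against the same panel. The ±3 rule is
  nominal, not exact, at this panel size — visible in the package's own
  null-calibration experiment, which measures ~1–2% rather than 0.27%.
  A larger panel tightens this toward the Gaussian tail.
- **Tumor fraction** assumes the dominant aberration is single-copy; a
  two-copy gain halves the true $f$ relative to the estimate. Estimates at
  $f \lesssim 0.05$ are flagged rather than reported.
- The consensus rule (breakpoint union + re-merge) is a documented,
  conservative stand-in for ensemble segmentation summaries whose original
  combination rule is unspecified.

## Problem sizes used by the test-suite experiments

Null calibration uses 20 controls + 20 held-out nulls × 50 gene regions on
the 5,060-window fixture; power and guard experiments use 50 replicates,
tumor-fraction recovery 20 replicates per $f \in \{0.1, 0.2, 0.3, 0.5\}$
(single-copy gain of a whole fixture chromosome — at 1/10 scale one fixture
chromosome has fewer windows than a mid-size real arm has on the full
50,000-window grid, so this is the conservative scaled analog of an arm
gain); segmenter-oracle sweeps use 500 series of length ≤ 30. These sizes
keep the whole suite within a few minutes on one CPU while leaving
Monte-Carlo error well inside the asserted margins.
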