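# imsvoc

Cross-validated discrimination of gas chromatography–ion mobility
spectrometry (GC-IMS) volatile organic compound (VOC) profiles.

## What problem this solves

GC-IMS measures the VOC headspace of a biological sample (faeces, urine,
breath) as a dense two-dimensional intensity map: one axis is GC retention
time, the other is IMS drift time. In volatolomics case–control studies —
for example distinguishing paediatric inflammatory bowel disease from
symptomatic non-IBD controls — these maps are compared between two groups
of subjects to ask whether the VOC *pattern* discriminates the groups, and
how well. The chemical content is sparse: most of the map is background
plus the reactant ion peak (RIP), the intense vertical line produced by
continuous ionisation of the carrier gas.

`imsvoc` implements the full desk-scale analysis cycle for such studies:

1. **Synthetic cohorts** (`simulate_cohort()`) — spectra built as baseline
   + RIP column profile + separable 2D Gaussian VOC peaks + Gaussian
   noise, with a configurable subset of peaks carrying a multiplicative
   class effect. The planted peaks are recorded as ground truth, so every
   downstream stage is testable without instrument data.
2. **Preprocessing** (`preprocess_cohort()`) — the standard
   dimensionality-reduction chain with one shared setting for all
   samples: crop to the informative region, subtract a RIP line taken
   from a peak-free retention window, zero everything below a small
   static threshold.
3. **Leakage-guarded cross-validation** (`run_cv()`) — spectra are
   flattened to pixel features; in each of k (default 10) stratified
   folds, features are ranked by two-sided Wilcoxon rank-sum p-value
   *computed on the training folds only*, the top features (default 50)
   feed an L1-penalised logistic regression (penalty tuned by inner CV)
   or a gradient-boosted tree ensemble, and the held-out samples receive
   out-of-fold class probabilities, pooled into one vector.
4. **Diagnostics** (`build_report()`) — from the pooled probabilities:
   AUC (the Mann–Whitney pair statistic), 95% CI (DeLong by default, or
   Hanley–McNeil), a rank-sum p-value against AUC = 0.5, the
   Youden-optimal cut-off and its sensitivity, specificity, PPV and NPV.
5. **Design calculation** (`ci_width_for_design()`) — the expected width
   of a two-sided AUC confidence interval for planned group sizes, via
   the Hanley–McNeil standard error

   SE² = [A(1−A) + (n₁−1)(Q₁−A²) + (n₂−1)(Q₂−A²)] / (n₁·n₂),
   Q₁ = A/(2−A), Q₂ = 2A²/(1+A),

   e.g. 123 cases and 62 controls at an anticipated AUC of 0.87 give a
   95% CI width of 0.10.

## Worked example

```r
library(imsvoc)

cfg <- read_run_config(system.file("extdata", "example_run.yaml",
                                   package = "imsvoc"))
report <- run_end_to_end(cfg)
print(report)
#> AUC (95% CI): 0.98 (0.95-1.00), p = 1.9e-07
#> cut-off 0.6: sensitivity 0.95, specificity 0.95, PPV 0.95, NPV 0.95 (n = 20/20)

round(ci_width_for_design(0.87, 123, 62), 4)
#> [1] 0.0995
```

The example config simulates 20 + 20 samples on a 32 × 32 grid with three
peaks whose intensity is twice as high in class 1 (`class_effect: 2`, with
40% per-sample lognormal variation and noise), so the pipeline recovers a
near-perfect separation: pooled out-of-fold AUC 0.98 with 95% DeLong CI
(0.95–1.00), and at the Youden-optimal probability cut-off of 0.6 all four
classification rates are 0.95. The second line is the design calculation:
at an anticipated AUC of 0.87, groups of 123 and 62 give an expected 95%
CI width of 0.0995 ≈ 0.10.

The same stages are scriptable from a shell via the thin CLI wrapper
(`system.file("cli", "imsvoc", package = "imsvoc")`) with subcommands
`simulate`, `preprocess`, `analyze`, `report`, `power` and `run`; cohorts
travel as per-sample CSV matrices plus a `manifest.tsv`.

## Scope

Binary comparisons only, as in the usual case–control design. The package
does not model ion chemistry (monomer/dimer formation, RIP depletion),
does not read vendor binary formats (export spectra to CSV first), and
performs no chemical identification of discriminating pixels — selected
features are statistical, not annotated compounds. See the methods
vignette (`vignettes/gcims-voc-pipeline.Rmd`) for the model, parameter
choices, and known limitations, including the anti-conservativeness of
pooled cross-validation p-values.
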