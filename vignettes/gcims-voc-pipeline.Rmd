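---
title: "Methods: simulation, preprocessing and cross-validated discrimination of GC-IMS VOC profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and cross-validated discrimination of GC-IMS VOC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsvoc)
```

This vignette documents the statistical model behind `imsvoc`, the
parameters that matter, the choices made where the design was genuinely
open, and what the package's validation does and does not establish.

## The measurement and its simulation model

A GC-IMS instrument separates a sample's volatile headspace first by GC
retention time, then by ion drift time, producing per sample a dense
matrix of ion intensities. Axes are stored normalised to 0–100, the
orientation in which such maps are usually displayed and cropped. Three
structural elements dominate real output:

* the **reactant ion peak (RIP)** — a high-intensity line at a fixed
  drift position spanning all retention times, produced by continuous
  ionisation of the carrier gas;
* **VOC peaks** — localised intensity blobs, concentrated at low
  retention and low drift because most detectable compounds are small
  and elute early;
* **background noise** around a baseline.

`simulate_spectrum()` composes exactly these elements:

$$I(r, d) = b + A_{\mathrm{RIP}} \, J \, e^{-(d-d_0)^2/2w_d^2}
  + \sum_p a_p \, \rho_p^{\,y} \, L_p \,
    e^{-(r-r_p)^2/2\sigma_{r,p}^2} e^{-(d-d_p)^2/2\sigma_{d,p}^2}
  + \varepsilon(r,d), \qquad I \ge 0,$$

where $y \in \{0,1\}$ is the class label, $\rho_p$ the multiplicative
class effect of peak $p$ (the planted ground truth; $\rho_p = 1$ means
non-discriminative), $J$ and $L_p$ mean-one lognormal factors for
per-injection RIP jitter and per-sample biological variation, and
$\varepsilon \sim N(0, \sigma^2)$ additive noise. Negative values are
clamped to zero, as detectors report non-negative counts.

Design choices, each made once:

* **Separable 2D Gaussians** for peaks: they match the blob appearance of
  real topographic maps and make every downstream check verifiable
  against a closed form.
* **Lognormal amplitude variation** (parameterised by a coefficient of
  variation) rather than additive noise on amplitudes: intensities stay
  positive, and a multiplicative class effect composes naturally.
* **Default cohort sizes 75 / 109**, the control/case sizes typical of a
  single-centre paediatric IBD volatolomics study.
* **Default peak placement** random in the lower-left quadrant, seeded.
* **Default class effect 2** for discriminative peaks in
  `default_peaks()`. No published effect-size estimates exist for real
  faecal VOCs (instrument studies report pattern-level AUCs, not
  per-compound ratios), so this default is an arbitrary but recoverable
  choice and is flagged as such here and in the function documentation.

What the generator does *not* emulate: monomer/dimer ion chemistry, RIP
depletion under analyte load, GC carryover, retention-time drift between
injections, and heteroscedastic detector noise. Consequences for
interpretation are discussed at the end.

## Preprocessing: crop, RIP subtraction, static threshold

Real pipelines reduce the raw map (millions of points) to its informative
region with settings **shared across all samples**; `preprocess_cohort()`
enforces that uniformity and logs the settings used. The order is fixed:
crop, then RIP line subtraction, then threshold.

* **Crop** keeps axis coordinates in half-open windows $[lo, hi)$, so
  adjacent windows tile without overlap. The window comes from
  configuration; choosing it is a judgement call on real data (users can
  `plot()` a spectrum), not an automated step.
* **RIP line**: the mean over the rows of a retention window that
  contains the RIP but no chemical information, subtracted from every
  row, negatives clamped at zero. Two sharing semantics exist because the
  convention differs between labs: `per_sample` (default) recomputes the
  line from each sample's own rows at the globally fixed window — RIP
  amplitude varies per injection, so this removes it more completely —
  while `global` subtracts one literal line taken from the cohort's mean
  spectrum from every file. When no window is given, the top 5% of the
  cropped retention rows (at least one row) is used; late retention rows
  are typically peak-free.
* **Threshold**: intensities strictly below $\tau$ become zero ("below"
  is read strictly, so values equal to $\tau$ survive). When $\tau$ is
  not supplied it is set to $3\times$ the median of the *positive*
  RIP-subtracted intensities, one value for the whole cohort. The median
  is taken over positive values only because clamping puts roughly half
  of all background pixels at exactly zero, which would otherwise drag
  the median — and hence the threshold — to zero. Both the window and
  the threshold rule are implementation defaults, not published values.

The chain preserves non-negativity at every stage and is idempotent on
noise-free data; with noise, a second pass changes at most the few
surviving pixels in the line window.

## The leakage-guarded cross-validated pipeline

Preprocessed spectra are flattened row-major into a samples × pixels
feature table. The discrimination procedure is:

1. assign samples to $k = 10$ folds (stratified by class, fold sizes
   within one of each other);
2. per fold: rank all pixel features by two-sided Wilcoxon rank-sum
   p-value comparing the two classes **on the nine training folds
   only** — the validation fold never influences which features are
   kept (ties in $p$ break by ascending pixel index, for determinism);
3. fit the classifier on the selected training columns — either
   `sparse_logistic` (L1-penalised logistic regression, penalty chosen
   by an inner 5-fold CV run inside the training fold, preserving the
   leakage guarantee) or `gradient_boosting` (trees of depth 3, 200
   rounds, learning rate 0.1, row subsample 0.8, exact greedy splits,
   seeded) — and predict class-1 probabilities for the held-out fold;
4. pool the out-of-fold probabilities into one vector and compute a
   single ROC analysis from it.

Parameters that matter:

* `n_top_features` (default 50): published pipelines of this type rarely
  state how many "top features" are kept; the default is a deliberate
  round number and should be treated as a tuning choice.
* Classifier hyperparameters are fixed, not tuned per dataset: at
  desk-scale $n$ there is not enough data to tune trees honestly inside
  the training folds, and fixed seeded settings keep runs reproducible.
  Exact greedy splits are used for the boosted trees because histogram
  binning places split points at training-data bin edges, which at small
  $n$ can put held-out values lying fractionally outside the training
  range on the wrong side of a split.
* Pooling out-of-fold probabilities into one ROC (rather than averaging
  per-fold AUCs) matches how single AUCs with confidence intervals are
  reported in practice; per-fold AUCs at these fold sizes (≈ 8–18
  samples) would be too unstable to average meaningfully.

The rank-sum machinery: p-values use the exact U distribution when the
combined sample size is ≤ 12 with no ties, and the normal approximation
with tie and continuity correction otherwise (the convention of classical
two-sample software). The per-feature scan `ranksum_pvalues()` is a
vectorised implementation of the approximate branch, verified in the test
suite to agree with the scalar test to machine precision.

## Diagnostics and the design calculation

From pooled probabilities, `build_report()` composes the standard
diagnostic row:

* **AUC** as the Mann–Whitney pair statistic (concordant pairs + half
  ties over all case–control pairs), computed from midranks; the ROC
  curve is built with the prediction rule score ≥ cutoff, and its
  trapezoidal area equals the pair statistic exactly, ties included.
* **95% CI**: DeLong's covariance estimator by default — the standard
  for empirical AUCs — with the Hanley–McNeil closed form as an
  alternative; the two agree within a few percent relative width at
  moderate AUCs and balanced $n$.
* **p-value**: the two-sided rank-sum test of the score distributions,
  i.e. a test of AUC = 0.5 (see the caveat below).
* **Optimum cut-off** by Youden's $J =$ sensitivity + specificity − 1;
  $J$ values within $10^{-9}$ count as tied (rate arithmetic produces
  equal fractions by different floating-point routes), ties break by
  higher specificity, then lower cutoff.
* **Sensitivity, specificity, PPV, NPV** from the observed confusion
  table at that cut-off; predictive values therefore reflect the study's
  prevalence, and ratios with empty denominators are reported as `NaN`,
  never silently as 0.

The design calculation `ci_width_for_design(auc, n1, n2)` returns
$2 z_{0.975} \cdot \mathrm{SE}_{\mathrm{HM}}$, the expected two-sided CI
width at the anticipated AUC; the Hanley–McNeil form is used here (not
DeLong) because a design-stage calculation has no data to estimate a
covariance from. Anticipated AUCs are restricted to $[0.5, 1)$ by design
convention. At AUC 0.87 with groups 123 and 62 the width is 0.0995 ≈
0.10; the acceptance script cross-checks this against a bootstrap on
binormal scores.

## Validation: what the checks establish

The test suite and `scripts/acceptance.R` validate, at the problem sizes
given in parentheses (chosen to exercise each property at desk scale):

* closed-form agreement of noise-free simulated spectra with the model
  at every pixel, and of preprocessed peak centres with their analytic
  values (41 × 41 grids);
* exact equivalence of the trapezoidal ROC area with brute-force pair
  counting (1000 random score sets, $n \le 200$) and of the exact
  rank-sum branch with full enumeration (all two-group splits of up to
  10 distinct values);
* the **leakage sentinel**: on pure-noise cohorts (60 samples × 2025
  pixels, 20 replicates) the guarded pipeline's mean out-of-fold AUC
  stays near 0.5 while a deliberately leaky variant — identical except
  that features are selected on the full table before cross-validation —
  inflates to ≈ 0.85. The wrong variant lives only in the tests and the
  acceptance script, as a negative control;
* **planted-effect recovery**: three peaks with class effect 3 at 40 +
  40 samples and noise at 10% of peak amplitude give pooled out-of-fold
  AUC > 0.9, and the planted centre pixels appear among the 50 selected
  features in at least 9 of 10 folds;
* DeLong interval coverage ≈ 95% on binormal scores (1000 replicates);
  type-I error of the rank-sum test ≤ 7% on i.i.d. null scores (500
  replicates).

Because the generator omits the real-data complications listed above,
passing these checks shows the *procedure* is correct and leakage-free —
it does not show that any particular real cohort is separable, and
printed diagnostic values from instrument studies are not reproducible
from simulation.

## Known limitation: pooled CV p-values are anti-conservative

One validation target fails by design of the method itself, and users
should know about it. The report's p-value applies a rank-sum test to the
pooled out-of-fold probabilities as if they were 100-odd exchangeable
scores. They are not: each sample is scored by a model trained on a 90%
subset overlapping every other fold's subset, so fold-level model
randomness adds variance that the rank test does not account for. On
full-pipeline null simulations (all class effects 1, with RIP, noise and
preprocessing; 30 + 30 samples; 100 replicates) the package's own null
study measures an empirical standard deviation of the null AUC of ≈ 0.09
against the ≈ 0.058 the rank test assumes, and a type-I error of ≈ 15%
at nominal 5% — for both classifiers and across cohort sizes, while the
same test on i.i.d. scores is calibrated. The p-value is therefore
reported as the field reports it, but small p-values near the 0.05
boundary should be read with this inflation in mind; a label-permutation
reference distribution (re-running the entire CV per permutation) is the
principled fix and is deliberately out of scope at desk-scale runtimes.

Other limitations: binary class labels only (multi-group designs are run
as separate pairwise comparisons, with no multiplicity correction, as is
conventional in this literature); no vendor binary format ingestion; no
chemical identification of selected pixels.
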