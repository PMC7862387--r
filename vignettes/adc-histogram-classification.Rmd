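---
title: "Discriminating posterior fossa tumours from ADC histograms: methods"
author: "pfADC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating posterior fossa tumours from ADC histograms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfADC)
```

## The problem

Medulloblastoma (MB), ependymoma (EP) and pilocytic astrocytoma (PA)
account for most paediatric posterior fossa tumours, and their preferred
treatments differ enough that a non-invasive hint at the diagnosis before
surgery is clinically valuable. Diffusion-weighted MRI offers one: the
apparent diffusion coefficient (ADC) is depressed in densely cellular
tumours (MB), elevated in microcystic ones (PA), and intermediate in EP.
pfADC implements the full quantitative chain for this discrimination —
ADC map computation, ROI histogram analysis, feature extraction,
PCA-reduced classification, ROC cutoff analysis and inter-rater
agreement statistics — together with a calibrated synthetic DWI cohort
generator so the chain can be exercised and validated end-to-end without
patient data.

## ADC maps

With two acquisitions per voxel, unweighted signal $S_0$ and
diffusion-weighted signal $S_b$ at weighting $b$ (here 1000 s/mm^2^),
the mono-exponential model $S_b = S_0 e^{-b\cdot ADC}$ gives

$$ADC = \frac{\ln(S_0/S_b)}{b},$$

which is exactly the least-squares slope of $\ln S$ against $-b$ through
the two points (`computeADC` and the tests assert this identity).
Numerical choices:

* voxels with a non-positive signal in either volume cannot be fitted;
  they are flagged invalid and excluded downstream, never clamped;
* negative ADC (noise pushing $S_b$ above $S_0$) is retained and
  counted; since the histogram grid starts at 0, such voxels end up in
  the out-of-range count rather than biasing the low quantiles through
  clipping;
* no smoothing or registration is applied — the inputs are assumed
  co-registered.

`qcPair` screens a pair before analysis and flags it when the
negative-ADC fraction inside a supplied mask exceeds 5% (configurable),
a symptom of artefact or mis-registration.

## Histograms and metrics

ROI ADC values are binned into a fixed grid of 180 bins of width
0.022×10^-3^ mm^2^/s and normalised to unit area, making tumours of
different sizes directly comparable. The grid needs an origin, which we
fix at 0: it is the physical ADC floor, and 180 × 0.022 = 3.96×10^-3^
mm^2^/s comfortably covers the observed per-tumour maxima. The last bin
is closed so the top edge is not silently lost; everything outside the
grid is counted, not dropped.

The per-case feature vector holds 22 values: min, max, mean, median,
variance, skewness, Pearson kurtosis, and 15 quantiles (5th–90th). Two
conventions needed fixing where the field uses several:

* **Kurtosis** is reported in the Pearson (non-excess) convention,
  $m_4/m_2^2$, under which a Gaussian scores 3 — consistent with
  reference PA values sitting essentially at 3. A switch
  (`excessKurtosis = TRUE`) is provided.
* **Quantiles** use linear interpolation of the empirical distribution
  (R type 7), the common default; with hundreds to thousands of voxels
  per ROI the estimator choice is immaterial.

Metrics are computed from the raw voxel values, not re-derived from the
binned densities: binned moments would be quantised by up to one bin
width, and the tests demonstrate the discrepancy on a deliberately
coarse grid. Mean histograms across cases use the per-bin arithmetic
mean and the per-bin *population* SD (the error bars describe the
spread of the cases at hand, not an inference about a wider population).

## Classification

The metric table is z-scored per column and reduced by PCA to the
smallest number of components covering 95% of the variance, capped at
10. Two classifiers are run on the components:

* **Gaussian naive Bayes** (authored in-package): per class and
  component a univariate Gaussian, priors from class frequencies,
  posterior by log-density summation. Within-class variances are
  floored at 10^-9^ times the pooled within-class variance so a
  degenerate class cannot yield infinite densities; argmax ties break
  towards the lexicographically first class name.
* **Random forest** via the randomForest package: 100 trees, Gini
  splits, $\lfloor\sqrt{d}\rfloor$ candidate features per split, seeded
  for determinism. The 100-tree default is the modern convention; it is
  configuration-exposed.

Evaluation is stratified 10-fold cross-validation with out-of-fold
predictions pooled into a single confusion matrix, from which per-class
recalls, overall accuracy (trace/total) and balanced accuracy (mean
recall) are computed. Two deliberate design decisions:

* **PCA is fitted on the full data before cross-validation.** This
  replicates the reference processing order and leaks a small amount of
  unlabeled test-set structure into the transform. `pcaInFold = TRUE`
  provides the leak-free variant; reproduction first, improvement
  optionally.
* **Columns are z-scored before PCA.** The metrics mix units
  (mm^2^/s, squared units, dimensionless); unscaled PCA would be
  dominated by whichever metric happens to have the largest numeric
  variance.

Fold assignment, forest fitting and the generator all derive from
explicit seeds, so every cross-validation result is a pure function of
(data, configuration, seed); accuracies can be averaged over seed
replicates (`crossValidateReplicates`) to tame fold noise.

## Univariate statistics

`rocCutoff` builds the empirical ROC for mean ADC between EP (positive,
higher ADC; called positive when mean ADC exceeds the threshold) and MB,
using midpoint thresholds between the distinct pooled values. AUC is the
trapezoidal area, identical to the Mann–Whitney $U/(n_1 n_2)$ statistic
(asserted exhaustively on small instances). The operating cutoff
maximises Youden's $J = sens + spec - 1$, ties resolving to the lower
threshold; raw counts are reported alongside the percentages so readers
can audit the arithmetic. `onewayANOVA` is the classic fixed-effects
one-way ANOVA (via `stats::oneway.test`, equal variances), which for two
groups equals the squared pooled t statistic. `interraterAgreement`
reports Pearson r and Bland–Altman statistics, with the repeatability
coefficient defined as 1.96 × SD of the paired differences and paired
two-tailed t-tests per metric under a Bonferroni threshold of
$0.05/22$ for the rater comparison — the tests are paired because the
two raters delineate the same tumours.

## The synthetic cohort generator

The generator exists so the whole pipeline can be tested against known
ground truth; its defaults are calibrated to published multicentre
per-tumour statistics for the three types (see
`posteriorFossaParams()`): cohort composition 55 MB / 26 EP / 36 PA,
between-patient mean ADC 0.870 ± 0.154, 1.126 ± 0.155 and
1.656 ± 0.290 ×10^-3^ mm^2^/s, within-tumour variances 1.00×10^-7^,
7.89×10^-8^ and 9.49×10^-8^ (mm^2^/s)^2^ and within-tumour skews
1.40 ± 0.60, 1.34 ± 1.13, 0.70 ± 0.83.

Per case:

1. a patient-level mean ADC is drawn
   $\mu_i \sim N(\text{meanADC}, \text{sdMeanADC})$;
2. the within-tumour voxel distribution is a **shifted gamma** matched
   in closed form to (mean, SD, skew): $k = (2/s)^2$,
   $\theta = \sigma s/2$, shift $= \mu - k\theta$. The gamma family was
   chosen because observed within-tumour skews reach 1.4, beyond the
   skew-normal ceiling (<1). Kurtosis is therefore *not* an independent
   dial: the family implies $3 + 1.5\,s^2$ — a known, documented
   approximation (it overshoots for MB, matches EP well);
3. draws below 0 are truncated to 0; the rate is logged and a warning
   raised above 1%;
4. signals follow the forward model with constant baseline $S_0$ (1000
   by default) and tissue-like background (ADC 0.8×10^-3^ mm^2^/s), and
   **Rician noise** — the physically correct magnitude-MRI noise — is
   applied to both volumes. The default sigma of 25 gives a b = 0 SNR
   of 40; sigma = 0 is reserved for exact forward/inverse tests, which
   recover truth to better than 10^-12^ relative error;
5. the ROI is a random ellipsoid of 500–5000 voxels (tumour sizes are
   not published; this covers roughly 1–10 cm^3^ at typical DWI
   resolution).

Two dispersion choices go beyond a literal reading of the published
point values, and were fixed a priori:

* **Per-case skewness is drawn lognormal** with the published
  between-patient mean and SD (support > 0 preserves the gamma match
  and, unlike a truncated normal, leaves the between-case mean skewness
  unbiased). A shape fixed per type would contradict the large
  published between-patient SDs of skew and kurtosis and would turn the
  shape metrics into near-noiseless class fingerprints.
* **Per-case within-tumour variance is drawn lognormal with CV 0.5**
  around the published value. No between-patient spread is published
  for the variance, but the source cohort spans 12 hospitals and 18
  scanners; treating the variance as identical in every patient would
  again be unrealistically clean. CV 0.5 is our single a-priori choice
  of "multicentre-realistic" heterogeneity.

What the generator does *not* emulate: anatomy (background is uniform
tissue), cysts/oedema sub-regions, scanner- or field-strength-specific
bias, partial-volume effects at the ROI boundary, and any correlation
between tumour size and type. Passing tests therefore demonstrate that
the *pipeline arithmetic* is correct and that the *statistical
machinery* recovers known inputs at realistic noise levels — not that
the classifier would achieve the same numbers on real patients.

## Problem sizes used in validation

The validation suite runs the generator at the reference cohort size
(117 cases) for the end-to-end checks, averaging cross-validated
accuracy, ROC cutoff and sensitivity over 10 cohort seeds; calibration
round-trips use 200 noiseless cases per type (3-SE acceptance on the
mean, 10% on variance and skewness); the ANOVA significance rate uses
100 replicate cohorts; unit tests use miniature volumes
(16×16×12, ROIs of 60–150 voxels) to keep the suite fast.

## Known limitations

* The two-point ADC fit cannot separate perfusion (IVIM) or kurtosis
  effects from diffusion; multi-b fitting is out of scope.
* Gamma-implied kurtosis diverges from the published MB/PA values, so
  the kurtosis feature carries less class information in simulation
  than it may in reality.
* With only histogram features, spatial information (location, texture,
  enhancement) is deliberately ignored.
* The cross-validated accuracies quoted anywhere in this package are
  properties of the synthetic cohorts under the calibration above;
  external validity requires real multicentre data.

## A worked miniature example

```{r example, eval = FALSE}
params <- posteriorFossaParams()
cases <- simulateCohort(params, counts = c(MB = 8L, EP = 8L, PA = 8L),
                        seed = 1, sigma = 25)
tab <- caseFeatureTable(cases)
cv <- crossValidate(tab, tab$label, classifier = "nb", k = 4, seed = 1)
cv$confusion
roc <- rocCutoff(tab$mean[tab$label == "EP"], tab$mean[tab$label == "MB"])
roc$optimalCutoff
```
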