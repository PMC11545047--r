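---
title: "Methods: hyperspectral defect grading with PLS-DA and repeated double cross-validation"
author: "hsigrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral defect grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsigrade)
```

## The problem

Small perishable fruit such as goji berries are graded by eye into ordinal
defect classes — sound, mild, moderate, severe — and hand sorting is slow and
inconsistent. Vis-NIR hyperspectral imaging (400–1000 nm, 5 nm sampling, 121
bands) records a full reflectance spectrum per pixel; one mean spectrum per
fruit then feeds a chemometric classifier. `hsigrade` implements that whole
chain — simulation, spectral extraction, pre-processing, PLS-DA with CovSel
variable selection, repeated double cross-validation (rDCV), and the standard
performance metrics — so that every stage is testable without proprietary
instrument data.

## The synthetic population

No public spectra exist for this task, so the package ships a seeded
generator (`generate_spectra()`, `generate_hypercube()`) built from the
band–chemistry associations reported for defective berries: carotenoid
pigments over 400–680 nm, water status near 715–750 nm, and sugar-related
features at 820, 930 and 970 nm.

**Latent severity.** Each fruit of class rank $r \in \{1,2,3,4\}$ draws a
latent severity $s \sim N(r-1,\ \sigma_s^2)$ with $\sigma_s = 0.40$.
Neighbouring classes overlap in $s$, so classification errors fall almost
exclusively on adjacent grades — the error structure real graded populations
show, where a sensory panel assigns the class from the same underlying damage
continuum the spectrum reflects.

**Effect regions with distinct trajectories.** The clean spectrum is

$$x(\lambda) = b(\lambda) + \sum_e g_e(s)\, p_e(\lambda),$$

where $b$ is a fixed smooth template (logistic red edge plus Gaussian
absorption dips) and each region has a profile $p_e$ (sum of Gaussian bumps)
and a monotone response $g_e$: pigment loss saturates early
($g(s)=\min(s, 1.2)$), water status drifts steadily ($g(s)=s$), sugar loss
appears only at advanced damage ($g(s)=\max(s-1.5, 0)$). The distinct shapes
matter: if severity acted through a single shared profile, the four class
means would be collinear, and a linear classifier of the indicator matrix
could never carve four decision regions — the rare sound class would simply
never win the argmax. Real defect spectra are not collinear either: bruising,
pitting and mould each dominate a different region.

**Artifacts.** Each spectrum is corrupted as
$\text{gain}\cdot x + \text{offset} + \varepsilon$ with
gain $\sim N(1, 0.08^2)$ (multiplicative scatter), offset
$\sim N(0, 0.02^2)$ (additive baseline) and i.i.d. per-band noise
$\varepsilon \sim N(0, 0.0015^2)$. The gain/offset pair is exactly the
distortion MSC and SNV remove, which the tests exploit. The per-band noise is
deliberately small: a per-fruit spectrum is the mean of hundreds of pixels,
which suppresses white noise, and this matters because the second-derivative
pre-treatment amplifies exactly that component. Simulated cube pixels carry
four times the per-fruit noise.

**Narrow-band variants.** For variable-recovery experiments,
`narrowband_effects()` plants the severity signal at a chosen set of isolated
wavelengths. Each planted band expresses the severity score with independent
per-fruit jitter (default sd 0.5 severity units): without it the bands would
be exactly collinear and a greedy covariance selector would have no reason to
keep more than one of them, whereas distinct chemical markers in real fruit
vary semi-independently.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: instrument radiometric calibration and PSF,
wavelength-correlated (pink) noise, touching fruit, defect-type-specific
signatures beyond the three-region model, and any seasonal or varietal
variation. The synthetic cube scenes (elliptical fruit, one contiguous defect
patch, saturated glare pixels at reflectance 1.05) are stand-ins for the
morphology of a scanner tray, not renderings of real berries.

## Extraction

`segment_fruit()` thresholds a single reference band (default 800 nm, on the
NIR plateau where fruit/background contrast is strongest in the template) and
labels connected components via `EBImage::bwlabel`, ordering fruit row-major
by centroid. `exclude_glare()` removes pixels saturated in any band (default
level 0.98, below the simulated glare ceiling of 1.05 and above any sound
tissue). `exclude_defect_edges()` optionally removes pixels whose spatial
gradient magnitude (mean over bands) exceeds a threshold. The default
`extract_spectra()` averages all non-glare fruit pixels: whether defective
tissue itself enters the fruit's mean spectrum is genuinely ambiguous in
grading practice, so both behaviours are available and neither is asserted as
canonical — the defect-edge filter is off by default and the tests exercise
it separately. The per-fruit spectrum is the unweighted band-wise mean of the
retained pixels.

## Pre-processing

All operators are train/test-aware: `fit_pipeline()` learns every statistic
(MSC reference spectrum, column means) from training rows only and freezes
it, so applying the fitted pipeline to test spectra can never leak
information backwards.

* **SNV** standardizes each spectrum to mean 0 and *sample* (n−1) standard
  deviation 1. The n−1 convention is stated so worked examples are exact.
* **MSC** regresses each spectrum on a reference and removes the fitted gain
  and offset. The reference is the training-set mean spectrum — the standard
  convention when none is prescribed.
* **Savitzky–Golay** (default 15-point window, 3rd-order polynomial, 2nd
  derivative) is a local least-squares polynomial filter. The derivative is
  scaled by $1/\Delta\lambda^d$ (5 nm spacing) so loadings plot in physical
  units; a constant scale does not affect classification. Edge policy:
  truncation by default — $(w-1)/2 = 7$ bands are dropped at each end, so
  every output variable corresponds to a full centred window and remains
  interpretable as a wavelength; a refit-at-edges mode (evaluating the edge
  window's polynomial off-centre) keeps all bands when needed. The surviving
  band indices travel with the fitted pipeline.
* **Mean centering**, when present, must be the last step.

The default chain is MSC → SG(15, 3, 2nd) → mean centering.

## PLS-DA, CovSel, PCA

`fit_plsda()` regresses a 0/1 class-indicator (dummy) matrix on the spectra
with a bilinear PLS2 algorithm: at each component the X-weight vector is the
dominant left singular vector of $X^\top Y$ on the deflated data, scores are
deflated from both blocks, and coefficients are
$B = W(P^\top W)^{-1} Q^\top$. This variant is deterministic (no random
initialization; sign fixed by the largest weight element), makes successive
scores exactly orthogonal, and reproduces multivariate least squares when the
number of latent variables reaches the rank of $X$ — the oracle equivalence
the tests assert. Class assignment is by the largest predicted indicator
value, with ties broken toward the lower severity rank; no prior reweighting
is applied, matching common chemometric practice even under class imbalance.
A fixed indicator threshold (e.g. a canonical-score cut) is a visualization
device, not the decision rule.

`covsel()` greedily selects the variable maximizing
$\sum_k \mathrm{cov}(x_j, y_k)^2$, then projects all predictor and response
columns orthogonally to the winner before the next pick. Selection on
deflated data makes the chosen set complementary; the selected sets are
nested by construction, but the criterion sequence is not guaranteed
monotone and is not asserted to be. If deflation exhausts the usable signal
the search stops early with a warning.

`pca()` is SVD-based on column-centred data, with the usual
sign-convention fix and explained-variance fractions.

## Repeated double cross-validation

`run_rdcv()` wraps an outer loop (performance estimation) around an inner
loop (model selection), repeated `n_runs` times; the defaults are the study
design of 10 outer segments, 9 inner segments, 50 runs, i.e. 500 fitted outer
models. Design choices:

* **Stratified segments.** With 51 sound against 574 defective fruit an
  unstratified 10-fold split can lose the minority class from inner folds,
  so segment assignment is stratified by class (per class, shuffled indices
  dealt cyclically into folds starting at a random fold). Unstratified
  assignment is available.
* **Inner selection.** For every outer split, candidate pre-treatments,
  numbers of latent variables and (optionally) numbers of CovSel variables
  are compared by pooled inner-loop predictions under the **mean per-class
  (macro) error** — the same "Error (%)" convention as the reporting module —
  with ties resolved toward fewer latent variables, then fewer variables,
  then the earlier pipeline in the candidate list. A nested-model shortcut
  evaluates all candidate LV counts from a single fit. When the candidate
  grid is a single combination the inner loop is skipped, since there is
  nothing to select.
* **Seeding.** One master seed spawns independent per-run sub-seeds, so
  results depend only on (data, config, seed).
* **Variable bookkeeping.** When selection is active, a single candidate
  pipeline is required so that variable indices mean the same wavelength in
  all 500 models; `selection_frequency()` is the fraction of models that
  chose each variable, and `stable_subset()` keeps those at or above the
  threshold (default 0.8 — "selected in at least 400 of 500 models").
  `rdcv_on_subset()` re-validates a fixed subset with the identical engine
  and selection disabled. The size of the stable subset is a data-dependent
  outcome, never a constant to be hit.
* **Canonical scores.** Each sample is scored once per run on the first
  latent variable of the model that held it out; `score_summary()` reports
  the mean over runs with a normal-approximation 95% interval,
  mean ± 1.96·sd/√n_runs.

## Metrics

Per-class sensitivity is $100\,TP_k/(TP_k+FN_k)$ from the confusion-matrix
row, specificity $100\,TN_k/(TN_k+FP_k)$ from the column complement; in a
two-class problem each class's specificity equals the other's sensitivity.
Overall accuracy is trace/total, algebraically the class-count-weighted mean
of sensitivities (`accuracy_from_sensitivities()` exposes the identity). The
"Error (%)" statistic is the **macro-average of per-class error rates**,
$\mathrm{mean}_k(100 - \mathrm{sens}_k)$ — the only definition consistent
with published two- and four-class tables of this design, whereas
100 − accuracy is not. Aggregation over runs is element-wise mean ± sample
standard deviation (zero for a single run). Displayed percentages are rounded
half-away-from-zero to one decimal; internal values keep full precision, so a
row of a row-percent confusion matrix can print to 99.9 or 100.1.

## Numerical and degenerate-input choices

* SNV refuses constant rows (naming them); MSC refuses a zero-variance
  reference and near-zero fitted gains (|a| < 1e−10).
* PLS deflation stops early if $X^\top Y$ or the score norm falls below
  1e−12 of scale; a model of reduced order is returned rather than noise
  components.
* CovSel masks columns whose deflated norm falls below 1e−12 of the maximum.
* Argmax ties (exact equality of predicted indicators) go to the lower
  severity rank, making grading conservative toward "sound".
* Glare exclusion uses ≥ comparisons so a pixel exactly at the saturation
  level is excluded.
* All file writes are write-temp-then-rename, so readers never observe a
  partial table.

## Problem sizes used by the tests

The validation suite runs entirely on simulated data at sizes chosen to keep
the full suite fast while preserving the study design: the 500-model
determinism check uses 200 samples with a single-candidate grid; the
permutation-null check uses 10 runs; the recovery experiment plants 10
narrow bands (jitter 0.7, delta 0.08) among 121 in a 200-sample two-class
set and runs 5 × 10 models with CovSel grids {10, 15, 20} variables and
{3, 5} latent variables; the four-class error-structure check uses the full
default population (625 fruit) at 5 runs with latent-variable grid
{4, 6, 8}. These sizes are the package's own choices and are stated here so
results are reproducible, not tuned per machine.

## Known limitations

* The classifier is linear in the (pre-processed) spectra; strongly
  non-linear class boundaries would need kernel or tree-based extensions
  that are out of scope.
* Argmax on indicator regressions is prior-sensitive: with heavy imbalance
  the minority class's decision region shrinks. The simulator's
  multi-trajectory effect design keeps the four regions non-degenerate, but
  on other data a prior correction (not enabled by default) may be needed.
* Segmentation assumes non-touching fruit on a dark background; watershed
  separation of touching fruit is a non-goal.
* The synthetic generator validates the machinery, not the instrument:
  agreement of synthetic accuracies with published figures on real fruit is
  neither expected nor asserted.
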