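---
title: "Calibrating potato quality parameters from NIR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating potato quality parameters from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nircal)
```

## The problem

Dry matter (%) and reducing sugars (g/100 g) determine the industrial value
of potato tubers: dry matter drives frying yield, and reducing sugars drive
Maillard browning of fried products. Both are conventionally measured by
destructive laboratory assays. Near-infrared (NIR) diffuse-reflectance
spectroscopy in the 900--1700 nm window offers a non-destructive
alternative: O--H and C--H overtone/combination bands of water,
carbohydrates and sugars leave composition information in the spectrum of
the intact tuber, and a multivariate calibration maps spectra to
constituent values.

`nircal` implements that calibration workflow end to end: conversion of
reflectance to absorbance $\log_{10}(1/R)$ and replicate averaging,
scatter-correction and derivative pretreatments, modified partial least
squares (MPLS) regression with outlier elimination and six-subset
cross-validation, ranking of a pretreatment grid, and external validation
on a held-out sample set. A synthetic spectra generator reproduces the
statistical structure of a two-cultivar field study (89 samples, six
replicate scans each), so the entire pipeline is testable without
instrument data.

## The MPLS model

For a centred spectral matrix $X$ ($n$ samples $\times$ $p$ channels) and
centred constituent vector $y$, each factor $a$ is extracted as in NIPALS
PLS1:

$$ w_a \propto X^\top y, \quad \lVert w_a \rVert = 1, \quad
   t_a = X w_a, \quad p_a = X^\top t_a / t_a^\top t_a, \quad
   q_a = y^\top t_a / t_a^\top t_a, $$

followed by deflation $X \leftarrow X - t_a p_a^\top$ and
$y \leftarrow y - q_a t_a$. The *modification* that turns PLS into MPLS is
a standardization step after each factor: the residual spectral matrix is
divided column-wise by the standard deviation of the residuals at each
wavelength, so that subsequent factors weight all wavelengths on a common
residual scale. The scaling vectors are stored with the model, and
prediction replays centring, score projection, deflation and scaling in
exactly the fit order. With standardization off the recursion is exactly
NIPALS PLS1, which is how the implementation is cross-checked against a
brute-force oracle in the tests.

Two conventions matter and are deliberate:

* $y$ is centred but never variance-scaled, and $X$ is not auto-scaled
  before the first factor; standardization enters only through the
  per-factor residual scaling described above.
* Residual columns whose SD falls below $10^{-12}$ keep scale 1. Once a
  channel is numerically exhausted, dividing by its SD would amplify
  rounding noise without adding information.

The maximum factor count defaults to 16 and is capped at $n/3$; the count
actually used is chosen by cross-validation (below). Rank deficiency (a
zero-norm weight) stops extraction early and flags the model.

## Preprocessing

Scatter corrections:

* **SNV** -- per-spectrum z-scoring, $(x - \bar x)/s_x$, with the $n-1$
  SD denominator used everywhere in this package.
* **MSC** -- each spectrum regressed on a reference spectrum (the
  calibration-set mean by default), corrected as $(x - a)/b$. The
  reference is stored with the model so that validation spectra are
  corrected against the *calibration* reference, never one recomputed
  from the new set.
* **Detrend** -- subtraction of a least-squares polynomial in wavelength,
  order 2 (the standard detrend definition; the order is exposed as an
  argument). SNV-DT applies SNV first, then detrend.

The four-digit math-treatment code $(d, g, s_1, s_2)$ -- derivative
order, derivative gap, first and second smoothing window -- is applied as
smoothing over $s_1$ points, then $d$ applications of the gap difference
$y_i = x_{i+g} - x_{i}$, then smoothing over $s_2$ points. Three
conventions are our own choices, because the code notation fixes only the
digits, not the scheme:

* the derivative is a forward difference over single points $g$ channels
  apart (not segment means), the simplest scheme consistent with "the
  interval over which the derivative is calculated"; it is isolated in
  one operation so an alternative can be swapped in;
* smoothing is a running mean, not Savitzky--Golay, matching the
  "data points in an average or smoothing" reading of the third digit;
* the valid wavelength range shrinks at each step (no padding), and
  wavelengths are relabelled as window midpoints; the output length is
  $p - d\,g - (s_1 - 1) - (s_2 - 1)$. Code `0,0,1,1` is the identity.

Replicate scans are averaged *after* conversion to absorbance. Averaging
and the $\log$ transform do not commute (Jensen's inequality), so the
pipeline refuses to average in reflectance mode rather than silently
producing a biased mean spectrum.

## Outlier elimination

Two criteria, applied in up to two passes (a hard cap that prevents
unbounded trimming):

* **Spectral (GH)**: the squared Mahalanobis distance of each sample in
  the PCA score space that retains 99.6 % of spectral variance, divided
  by the number of components. Under this "global H" convention the mean
  GH of the calibration set is $(n-1)/n \approx 1$, and GH > 3 flags a
  sample. The score space, variance target and threshold are arguments.
* **Chemical (T)**: the standardized held-out residual
  $T_i = |y_i - \hat y_{cv,i}| / \mathrm{SECV}$, using cross-validated
  rather than fitted residuals so that a gross reference error cannot
  mask itself; $T \ge 2.5$ flags a sample.

A numerical guard: when SECV falls below $10^{-8}\,s_y$ the model is
numerically perfect and the T ratios are rounding noise over rounding
noise, so the chemical criterion is switched off for that pass.

One behaviour of the GH criterion is worth understanding before use: GH
is a leverage statistic. On data whose spectra are driven by a few latent
constituents, the score space is low-dimensional and samples with extreme
(but perfectly valid) composition have GH > 3 with appreciable
probability -- roughly $P(\chi^2_2 > 6) \approx 5\,\%$ per sample in a
two-component space. Removing a handful of composition-extreme samples
from clean data is therefore *expected* behaviour of the H = 3
convention, consistent with the handful of removals reported in practice
by chemometric software on real calibration sets. On noisy spectra the
99.6 % space is much higher-dimensional, GH concentrates near 1, and
clean samples are essentially never flagged. The procedure also refuses
to trim below a fittable sample count and flags the report as aborted
instead.

## Cross-validation and factor selection

The calibration set is partitioned at random (seeded) into six near-equal
subsets; each subset in turn is predicted by a model fitted on the other
five, at every candidate factor count. $\mathrm{SECV}(k)$ is the root
mean square held-out residual with denominator $n$. The selected count
minimizes SECV with ties resolved toward fewer factors; "tie" includes
agreement within a relative $10^{-8}$, because on noiseless data SECV is
flat at machine precision for every $k$ at or above the latent rank and
a strict argmin would pick an arbitrary large count.

Calibration statistics follow the conventional definitions:
$\mathrm{SEC} = \sqrt{\sum(y - \hat y)^2/(n - k - 1)}$, RSQ is the
squared Pearson correlation of reference and fitted values,
$\mathrm{RPD} = s_y/\mathrm{SECV}$, and the applicability range is the
mean $\pm 3$ SD of the retained reference values (reported together with
the observed extremes; the range is not clipped, matching how
chemometric software reports it).

The grid search runs outlier elimination, cross-validation and the
statistics block for each of 25 default treatments (five scatter modes
$\times$ five codes, covering the treatments that typically lead such
rankings for tuber constituents) and sorts by ascending SECV, then descending RSQ, then
declaration order. All candidates share one fold seed so the ranking
compares like with like.

## External validation

For validation residuals $e = y_{ref} - \hat y$ on $n$ held-out samples:
$\mathrm{bias} = \bar e$;
$\mathrm{RMSE} = \mathrm{SEP} = \sqrt{\sum e^2 / n}$ (uncorrected,
denominator $n$);
$\mathrm{SEP(C)} = \sqrt{\sum (e - \bar e)^2/(n-1)}$ (bias-corrected);
and the paired Student $t = \mathrm{bias}/(\mathrm{SEP(C)}/\sqrt n)$
with $n-1$ degrees of freedom. Under these definitions
$\mathrm{SEP}^2 = \mathrm{bias}^2 + \mathrm{SEP(C)}^2 (n-1)/n$ holds
identically, which the tests exploit. "Mean residual" is reported as the
mean *absolute* residual (the signed mean equals the bias and is kept
alongside): in a validation table a mean residual of similar magnitude to
the RMSE indicates magnitudes, not signed means. The verdict "no
difference between reference and NIR values" corresponds to $p > 0.05$.

The cultivar comparison of reference values uses the Kruskal--Wallis rank
test with tie correction; identical values in every group return
$H = 0, p = 1$ by convention.

## The synthetic generator

`syntheticConfig()` encodes the emulated study design:

* 89 samples -- Kennebec ($n = 48$) and Agria ($n = 41$) -- with dry
  matter and reducing sugars drawn from per-cultivar truncated normal
  distributions (mean/SD/min/max as tabulated for the study populations:
  Kennebec 19.88/1.63/16.00/22.10 % dry matter and 0.23/0.09/0.15/0.49
  g/100 g sugars; Agria 20.19/1.04/17.30/22.20 and 0.15/0.04/0.10/0.37).
  Sampling is by rejection (resample until in bounds), which honours the
  tabulated extremes without distorting the mean under mild truncation.
* a 900--1700 nm grid at 6 nm steps, closed at the start and including
  the end point only when it lies on the grid: 134 channels ending at
  1698 nm. The study instrument reports a 128-pixel detector while its
  stated range and step imply about 134 channels; rather than resolve
  that discrepancy the grid is plain configuration.
* six replicate scans per sample (534 spectra).
* a Beer--Lambert-style mixture: each sample's latent absorbance is
  $\sum_c \mathrm{conc}_c \times \sum_b A_b
  e^{-(\lambda-\mu_b)^2/2\sigma_b^2}$ plus a per-sample linear baseline.
  Water (concentration $100 - \mathrm{DM}$) carries bands near 970, 1190
  and 1450 nm; carbohydrate (DM) near 1200 and 1580 nm; sugars near 1430
  and 1690 nm. Each replicate is the latent spectrum under multiplicative
  scatter $(1 + s)$, plus a replicate offset and independent channel
  noise.

Default noise levels were fixed once, by design, so that the default
conditions land in the performance regime of a realistic intact-tuber
study rather than in a trivially easy one: channel noise of 0.05
absorbance units puts the cross-validated RSQ for dry matter in the
mid-range (about 0.7) and the sugar band amplitudes (0.20/0.15 per
g/100 g) put the reducing-sugars model near RPD 1.5. These defaults are
the study conditions of the test suite and are not adjusted per test.

What the generator does *not* emulate -- and hence what passing tests do
not demonstrate about real tubers: skin/peel optics and tissue
heterogeneity between the scanned surface and the assayed flesh,
wavelength-correlated instrument noise and drift, reference-assay error
as a separate term (it is absorbed into the spectral noise), and any
non-linearity of diffuse reflectance at high absorbance. The generator
validates the *chemometrics*, not the spectroscopy.

## Numerical choices and degenerate inputs

* SD denominator $n - 1$ everywhere (SNV, descriptive statistics,
  residual scaling), so oracles and implementation share one convention.
* Guards: SNV refuses constant spectra; MSC refuses slopes
  $|b| < 10^{-12}$; residual scalings below $10^{-12}$ become 1; SECV
  below $10^{-8}\,s_y$ disables the T criterion; reflectance must lie in
  $(0, 1]$ with the offending cell named.
* CSV interchange writes floats with 17 significant digits and model JSON
  uses 17 significant digits, so both round-trip binary64 exactly.
* Seeds: every stochastic step (reference draws, spectra noise, the
  70/19 split, fold assignment) takes an explicit seed; generation
  functions restore the caller's RNG state.

## Problem sizes in the test suite

The tests run the default 89-sample, 534-spectrum design for pipeline
checks, 20 x 30 random matrices (50 replicates) for the PLS oracle
comparison, 10 000 draws for the truncated-normal moment check, and 100
seeded replicates for the distributional checks (paired-t verdict rate,
cultivar comparison). These sizes keep the full suite around a minute
while leaving Monte-Carlo margins wide.

## Limitations

* The gap-derivative and smoothing conventions above are one reasonable
  reading of the four-digit code; proprietary implementations may differ
  in edge handling and derivative scheme, so coefficients are not
  expected to transfer between implementations.
* PLS1 only: one constituent per model (dry matter and reducing sugars
  are calibrated independently); no PLS2, kernel or sparse variants.
* Random calibration/validation splitting only; score-space sample
  selection algorithms (e.g. distance-based subset selection) are out of
  scope.
* No wavelength-interval selection, orthogonal signal correction or
  instrument-transfer standardization.
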