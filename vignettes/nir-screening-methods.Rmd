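---
title: "Methods: NIR screening of falsified and substandard medicines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR screening of falsified and substandard medicines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscreen)
```

## The screening problem

Falsified medicines contain none of their stated active pharmaceutical
ingredient (API); substandard ones contain it outside an accepted tolerance
band. Handheld diffuse-reflectance near-infrared (NIR) spectrometers working
in the 740–1,060 nm range can screen tablets non-destructively, but the
spectral features at these wavelengths are weak and heavily overlapped, so
everything rests on chemometrics. `nirscreen` implements that chemometric
layer end to end:

1. **Preprocessing** — replicate averaging, reflectance → absorbance
   (A = −log₁₀ R), Savitzky–Golay smoothing, second derivatives, and linear
   background subtraction.
2. **Authentication** — a spectral library-matching classifier: Mahalanobis
   distance of a second-derivative spectrum from the genuine-product cluster,
   with a binary acceptance threshold.
3. **Quantitation** — single-response NIPALS partial least squares regression
   (PLSR) of API content on smoothed, baseline-subtracted absorbance, with
   leave-one-out cross-validation (LOOCV) and a tolerance-band verdict.
4. **A synthetic generator** — no public spectra exist for the device class
   this emulates, so the package ships a Beer–Lambert world in which every
   stage is testable.

## The synthetic world

The generator's defaults describe one fixed, declared world; they are design
choices made once, not fitting targets.

**Signal model.** Each component (API or excipient) has a pure absorbance
signature built from Gaussian bands, ε(λ) = Σ_b a_b·exp(−(λ−c_b)²/2w_b²).
A tablet's absorbance is the Beer–Lambert sum Σ_i c_i ε_i(λ) plus an affine
instrument/batch baseline and Gaussian noise; reflectance is R = 10^(−A).
API signatures use three narrow bands (width 9 nm, amplitudes 0.45–0.75 AU);
the excipient is a broad low background. A falsified tablet either lacks the
APIs or replaces them with a "wrong compound" whose single band at 762 nm
sits more than three band-widths from every API band — the separable regime.

**Content model.** Quality-assured content varies through a common
tablet-mass factor drawn **uniformly** on 93–107 % of label (all components
of a dose scale together). Substandard samples have the affected component's
content drawn uniformly in a configured percent range (default 66–85).
Falsified samples carry 0 % for every API. The uniform (bounded) content
model matters: real tablet content uniformity is bounded by manufacturing
controls, and boundedness is what lets a distance threshold achieve exactly
100 % specificity run after run. A Gaussian content model would put ~1 % of
genuine samples beyond any chi-square(0.99)-style radius and make perfect
specificity a coin flip — an instructive difference between the two worlds.

**Noise model.** Per-scan absorbance noise sd 5×10⁻⁵ AU (a handheld-device
noise-floor convention; the real device's noise was never published), a
per-sample baseline offset/slope (0.01 AU, 2×10⁻⁵ AU/nm) and a per-batch
shared baseline offset (0.02 AU). All baseline terms are affine in λ, so the
second-derivative pipeline removes them *exactly*; they exist to give the
quantitative pipeline's background subtraction and the leave-batch-out
cross-validation something real to defeat.

A variance budget justifies the regime: in second-derivative space the
content factor contributes per-channel signal ≈ 2.5×10⁻⁴ AU/nm² at band
centres, while filtered scan noise (3-replicate average, window-11 filter)
contributes ≈ 2×10⁻⁶ — a ratio of ~10² per channel and ~500 in total
variance, so the top principal axis carries > 99.5 % of the class variance
and the retained dimension count is 1.

**What the generator does not emulate:** scattering and particle-size
effects (no multiplicative scatter component), wavelength-dependent
instrument response, tablet-position variability, coating signatures,
moisture bands, or degradation chemistry. A green test here shows the
algorithms are correct in a world obeying their assumptions, not that the
physical device achieves these numbers.

## Preprocessing choices

* **Savitzky–Golay defaults**: window 11 points, polynomial order 3,
  configurable. At 1-nm spacing an 11-point window spans roughly a band
  half-width, smoothing noise while distorting 9-nm bands by < 0.01 AU
  (asserted in the tests). Derivatives are scaled per nm (divide by
  spacing^deriv), so values are grid-independent. Edges are evaluated from
  the polynomial fitted to the terminal windows, keeping output length equal
  to input length and grids aligned across samples.
* **Background subtraction** for the quantitative pipeline is the straight
  line through the means of the first and last five points. The term is
  undefined in the source setting (dark current? baseline fit?); this
  convention is isolated behind the `baseline` switch. Smoothing runs before
  subtraction, matching the narrative order of the method description; since
  the filter reproduces affine functions exactly, the two orders differ only
  at the spectrum edges.
* The qualitative pipeline (average → absorbance → 2nd derivative) output is
  invariant to adding any affine function of λ — a property test, and the
  reason batch baselines cannot leak into authentication.

## Authentication design

With ~60 training spectra on a 321-point grid, the full-space covariance is
singular, so Mahalanobis distance is computed in a PCA subspace: k = the
smallest number of axes explaining ≥ `variance_kept` (default 0.99) of the
training variance, capped at n − 2, with optional shrinkage of the score
covariance toward (trace/k)·I (default 0.05). The acceptance radius is
√(χ²-quantile with k degrees of freedom).

The **threshold quantile defaults to 0.9999**, not 0.99. The rationale: the
classifier's job is screening, and synthetic falsifieds sit at Mahalanobis
distances ≥ 20 while genuine samples stay under ~3.6 even when the fold's
training set is as small as 18 samples (measured over 200 generator seeds
before the tests were frozen). At 0.99 the expected ~1 %-per-sample false
alarm rate makes 100 % specificity over a 60–100-sample study statistically
implausible — inconsistent with the perfect screening accuracy this method
family reports — while 0.9999 rejects only what is practically impossible
for the genuine class and keeps a > 5× sensitivity margin. The quantile is a
config knob; nothing downstream depends on the default.

Two exclusion rules are enforced, not advisory: falsified samples are
**refused** as training input (`fit_class_model` raises an error), because a
falsified product could have any composition; and leave-batch-out evaluation
never lets a batch train the model that judges it. Falsified test samples
are judged by a model trained on all quality-assured batches, since they
belong to no genuine batch. A distance exactly at the threshold is accepted
(documented tie rule). Single-batch brands are refused for batch-exclusion
cross-validation rather than silently downgraded.

## Quantitation design

PLSR uses the classical single-response NIPALS recursion with deflation of
both X and y, assembled into β = W(PᵀW)⁻¹q so prediction is one affine map.
Three latent components are the default. All headline numbers come from
LOOCV predictions; R² = 1 − SS_res/SS_tot on those predictions (it can be
negative when calibration fails, which is informative).

"Normalized residuals" are read as residuals in percent-of-label units —
truth and prediction are both already percentages of stated content, so no
further normalization applies. The 95 %-coverage half-width is
`factor × resid_sd` with **factor 2** (not 1.96): the convention by which a
residual SD of 7.4 % maps to a ±14.8 % claim; the factor is exposed as
`coverage_factor`. Tolerance-band verdicts use inclusive boundaries on the
85–115 % band by default, with the stricter 90–110 % pharmacopeia band one
argument away.

Principal components regression is kept (`fit_pcr`) as the comparison
method; the test-suite includes the classic constructed instance where PC1
is orthogonal to the concentration-relevant variation, so PCR at one
component fails while PLSR succeeds.

## Numerical and degenerate-input conventions

* Reflectance must lie in (0, 1]; non-positive values fail at construction,
  naming the offending wavelength. Generator defaults keep absorbance
  positive so this cannot trigger in simulated data.
* Savitzky–Golay requires a uniform grid (relative spacing tolerance 10⁻⁶)
  and odd windows; spectra shorter than the window are rejected.
* Identical training spectra (zero total variance) are a hard error in
  `fit_class_model`; constant y is a hard error in calibration.
* PLSR stops with an error when a requested component finds no residual
  covariance with y (a beyond the usable rank).
* Library generation is a pure function of its config (seed included); the
  caller's RNG state is saved and restored.
* Model JSON round-trips at full double precision; spectra CSVs render 12
  significant digits, keeping roundtrips within 10⁻⁹ relative error while
  staying byte-deterministic.

## Known limitations

The generator's realism caveats above are the main ones. Beyond those:
authentication is one-class per brand (no nearest-library multi-brand
assignment); there is no instrument-transfer or re-calibration support; the
bilayer model assumes the two layers are optically independent when scanned
per side; and quantitation assumes the analyte's signature is present in the
spectra — when it is not (the amodiaquine-like case), the pipeline correctly
reports a near-zero LOOCV R² rather than a usable calibration, and the
tests pin that behaviour down as a feature.
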