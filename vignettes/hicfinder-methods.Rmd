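---
title: "Detecting hypoperfusion components in resting-state BOLD fMRI: models and conventions"
author: "hicfinder authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hypoperfusion components: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicfinder)
```

# The problem and the model

Gadolinium-based perfusion MRI delineates hypoperfused tissue in acute
stroke via the time-to-maximum (T~max~) of the tissue residue function,
but contrast injection is not always possible or desirable. The
contrast-free alternative exploited here rests on a physiological fact:
a systemic low-frequency oscillation (sLFO, roughly 0.01–0.1 Hz) rides on
the blood and sweeps through the brain, so BOLD fluctuations in tissue fed
by an occluded or stenosed artery arrive *late* — by several seconds in
acute stroke — and shift toward even lower frequencies.

Spatial ICA factorises the preprocessed 4D signal into spatial maps with
paired time courses under the assumption that the maps are mutually
independent and non-Gaussian over voxels. Because stroke hypoperfusion is
spatially confined (typically to one vascular territory) while both
neuronal resting-state networks and systemic vascular signals are
distributed, the delayed-perfusion signal tends to separate into its own
component — a *hypoperfusion independent component* (HIC). The package
identifies HICs by their feature signature and classifies them
automatically.

# Pipeline stages and their conventions

## Preprocessing

`preprocessBold()` applies, in order: discard of the first 4 volumes
(signal equilibration), per-voxel removal of linear and quadratic trends,
and volumetric Gaussian smoothing at 6 mm FWHM. The series is deliberately
left *temporally unfiltered*: the band-power features below need the full
spectrum. Two conventions were open and are fixed here as package
decisions: detrending projects onto an orthonormal polynomial basis
(numerically stable, idempotent to 1e-8), and smoothing uses constant
(replicate) extension at the volume boundary, which avoids rim attenuation
on the small phantom grids. Slice-timing correction and realignment are
standard-tool stages, not reproduced here; phantom volumes are generated
aligned.

## Decomposition

`spatialICA()` whitens the in-mask voxel × time matrix to `k` principal
components and runs a fixed-point non-Gaussianity maximisation (logcosh
contrast) with *symmetric* decorrelation — all components are updated
jointly, so no deflation ordering is imposed; the variant is recorded in
the output metadata. Three conventions resolve ambiguities the
decomposition leaves open:

* **Model order.** `estimateDimensionality()` compares the eigenvalue
  spectrum against the broken-stick null and keeps the leading run of
  super-null eigenvalues (clipped to the numerical rank, floored at 1).
  This approximates automatic Bayesian order selection without
  reproducing any specific prior; a user-supplied `k` bypasses it.
* **Sign.** Each component is oriented so its spatial map has nonnegative
  skewness — a deterministic resolution of the inherent ICA sign
  ambiguity (activation blobs come out positive).
* **Z-scaling.** Maps are standardised to mean 0, sd 1 over the mask
  before thresholding at |Z| > 2.33. Mixture-model-based Z calibration
  (as in some ICA suites) is *not* used; raw standardisation is simpler
  and monotone-equivalent for thresholding, but the absolute |Z| values
  differ from mixture-calibrated ones. One geometric consequence: a
  binary-ish source occupying fraction *p* of the mask standardises to
  roughly $(1-p)/\sqrt{p(1-p)}$ on its support, which drops below 2.33
  once *p* exceeds ~0.2. Sources are therefore only recoverable by the
  fixed threshold when they are a modest fraction of the brain — true of
  real single-territory lesions and of the phantom defaults.

## Feature extraction

For each component, `componentFeatureTable()` computes:

* **Delays** (`delayGlobal`, `delayVenous`): the lag in [−20, +20] s that
  maximises normalized cross-correlation between the component time
  course and the mean signal over the brain mask or the venous-sinus
  mask. Positive = component follows the reference. The integer-lag peak
  is refined by a parabola through the three neighbouring correlations;
  the ±20 s range accommodates the very long delays seen in acute stroke.
  Peaks on the search boundary are flagged.
* **Band powers** (`band1`…`band6`): percentage of periodogram power in
  0–0.01, 0.01–0.025, 0.025–0.05, 0.05–0.1, 0.1–0.15 and 0.15–0.2 Hz.
  The denominator is all non-DC power up to Nyquist (DC is excluded from
  numerator and denominator), so the six fractions sum to ≤ 100% and the
  deficit equals the power above 0.2 Hz; this makes fractions comparable
  across repetition times. No window is applied (plain FFT periodogram).
* **Territory occupancy** (`occupancy`): the percentage of the
  thresholded map inside its best-covered vascular territory, with a
  separate boolean for the >50% single-territory criterion. Components
  failing the criterion keep their computed percentage rather than being
  zeroed or dropped — discarding the information would silently remove
  candidate components; the flag lets callers filter if they wish. Exact
  ties break to the lower territory id.
* **Mean T~max~** (`meanTmax`, optional): mean T~max~ under the
  thresholded map. This feature validates HICs against perfusion imaging
  and is *not* part of the classifier's nine features.

Per subject, every feature is min–max normalized across that subject's
components: $z_i = (x_i - \min S)/(\max S - \min S)$. If all components
share a value the result is 0.5 with a degeneracy flag.

`timeShiftMap()` produces the companion voxelwise BOLD-lag map: pass 1
correlates every voxel against the global mean; later passes rebuild the
regressor as the mean of voxel time courses back-shifted by their current
delay estimates (3 passes by default). Voxels whose peak correlation falls
below 0.3 are reported missing — below that the lag estimate is mostly
noise.

## Classification

`fitHicModel()` fits a penalised logistic regression with elastic-net
mixing α = 0.5 — equal ridge/lasso weight, exposed as a flag since the
mixing value is a free choice — over a lambda path, choosing λ by
leave-one-out cross-validated deviance. LOO (rather than 10-fold or a
one-standard-error rule) maximises the use of the tiny 46-row balanced
training set. The probability threshold is frozen *at training time* by
maximising Youden's J over the LOO held-out probabilities: resubstitution
probabilities would be optimistically separated, and thresholding on test
data would leak. Ties in J break toward the lower threshold, favouring
sensitivity — the clinically safer error. No p-values are attached to the
coefficients; with penalised estimation no meaningful standard errors
exist, and feature importance is read from the odds ratios instead
(`oddsRatios()`, OR = e^coef, exactly 1 for penalised-away features).

`evaluateModel()` mirrors the heavy class imbalance of real component
shortlists: each of 50 iterations samples 5 HICs and 50 non-HICs from the
held-out pool and computes AUC (rank-based Mann–Whitney with midrank
ties — the probabilistic definition), sensitivity, specificity, balanced
accuracy and Cohen's kappa at the frozen threshold; medians over
iterations summarise. `runClassifierProtocol()` chains the whole protocol
(draw → normalize → balance 23+23 → fit → threshold → evaluate) from one
master seed.

## Quality control and validation

Framewise displacement is computed from backward differences of the six
realignment parameters, rotations converted to arc length at a 50 mm head
radius (the convention of the standard FD definition; a literal sum of
absolute parameter values would not be a displacement). A scan is flagged
as severely motion-affected when mean FD > 0.4 mm or max FD > 3 mm.
Spatial agreement uses the Dice coefficient, and
`identifyHicByOverlap()` names the component with the highest Dice against
a lesion mask (ties broken by |Z| mass inside the lesion). T~max~ maps can
have CSF artifacts removed by mask subtraction (`removeCsfArtifacts()`,
voxels set missing) before any overlap or mean computation.

# The phantom: what it emulates, what it does not

`simulateSubject()` builds, on an ellipsoidal brain with an 8-wedge
territory atlas (emulating the major arterial territories — bilateral
anterior/middle/posterior plus posterior-circulation divisions):

* a unit-sd sLFO, band-limited Gaussian noise in 0.01–0.1 Hz (a realistic
  broadband spectrum rather than a sum of sinusoids), present in every
  in-brain voxel;
* one or more HIC sources: a contiguous blob covering a configurable
  fraction (default 0.9) of one territory, carrying the *same* sLFO
  delayed by `delaySec` (default 7 s) via an exact fractional-sample
  Fourier phase shift, plus an extra band-limited oscillation below
  0.025 Hz scaled by `lfBoost` — the low-frequency shift of ischemic
  tissue;
* bilateral resting-state-network sources with independent 0.01–0.1 Hz
  time courses (default 2);
* Gaussian noise (default sd 0.3 relative to the unit-sd sLFO — moderate),
  per-voxel linear/quadratic drift, and a slow-wander six-parameter
  motion trace;
* a matched T~max~ volume (~1.3 s background, lesion elevated by the
  injected delay) and lesion mask.

Acquisition defaults mirror a 3T stroke protocol: TR 2.3 s, 150 volumes,
3 mm voxels, on a 32 × 32 × 16 grid so one subject simulates in seconds.
The configuration validator requires the series to span at least twice the
20 s maximum tracked lag. The BOLD amplitude reduction in hypoperfused
tissue is not quantified in the literature values this package encodes, so
it is exposed as the free parameter `hicAmplitudeScale` (default 1, no
reduction) rather than fixed. Motion is emitted as a parameter trace only;
volumes are generated aligned, so realignment estimation is out of scope.

`simulateFeatureTable()` generates labelled feature vectors directly:
independent Gaussians per feature per class, with per-class means taken
from published cohort summaries (57 HICs, 471 non-HICs) and standard
deviations recovered from the 95% confidence intervals of the means as
$\mathrm{sd} = \mathrm{halfwidth}\cdot\sqrt{n}/1.96$
(`referenceFeatureMoments()`). Physical constraints are re-imposed after
drawing: occupancy clipped to [0, 100], negative band powers clipped at
zero with the row rescaled proportionally to keep its drawn total
(preserving the drawn band profile shape), mean T~max~ clipped at zero.

What the phantom does **not** emulate: hemodynamic response functions,
EPI distortion, cardiac/respiratory aliasing, partial-volume effects,
spatially varying noise, multi-echo acquisition, or the correlation
structure between features of real components (the feature generator
draws features independently). Passing tests on phantoms therefore
demonstrate that the estimators recover what the generative model
injects — delay, spectral shift, territory confinement — not that the
pipeline handles every artifact of clinical data.

# Numerical choices and degenerate inputs

* Delay estimation requires ≥ 30 samples and nonconstant signals; a flat
  reference is an error, a boundary peak is flagged, and the parabolic
  offset is clamped to ±half a sample.
* `minmaxNormalize()` returns 0.5 everywhere (flagged) when all values
  coincide; `detrendSeries()` of a constant series returns zeros.
* ICA restarts from a fresh random rotation up to 5 times on
  non-convergence (tolerance 1e-7 on the rotation update), then errors;
  `k` above the numerical matrix rank errors immediately.
* Empty thresholded maps are allowed and flagged; they produce occupancy
  0 with no territory and a missing mean T~max~.
* Youden candidates are midpoints of consecutive sorted unique
  probabilities; the classification rule is strictly "probability >
  threshold".
* Kappa with both raters constant and equal (chance agreement 1) is
  defined as 1; two empty masks have Dice 0 with a flag.

# Problem sizes used in the shipped checks

The test suite exercises the full pipeline at the phantom's native scale
(32 × 32 × 16 × 150, ~7,500 brain voxels): twenty seeded subjects for the
end-to-end recovery property, one subject for the time-shift-map
identities, and the full 57 + 471 feature-table protocol for the
classifier checks. These sizes keep a complete run in the low minutes on
one CPU while leaving every estimator identifiable (the lag grid spans
±8.7 samples at TR 2.3 s; the 146-point periodogram resolves the band
edges).

# Known limitations

* The wedge atlas is a geometric stand-in; real vascular territories are
  not angular sectors, and occupancy percentages on real data depend on
  the atlas used.
* Raw-standardised Z maps make the |Z| > 2.33 cut stricter for large
  sources than mixture-calibrated thresholding would be (see above);
  comparisons with ICA suites that calibrate Z against a noise model are
  monotone but not numerically identical.
* The classifier protocol draws features independently within class;
  real component features are correlated (e.g. the two delays), so
  synthetic-protocol metrics characterise the protocol, not clinical
  performance.
* With 5 test HICs per iteration, sensitivity is quantised to fifths and
  its median is sensitive to the seed near decision boundaries.
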