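---
title: "Video radiomics for HER2 status: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video radiomics for HER2 status: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

HER2 expression status (positive vs negative) guides targeted therapy in
breast cancer, but the reference assays (IHC/FISH) are invasive and sample
only part of a heterogeneous lesion. `vidradiomics` implements a
video-based radiomics pipeline that predicts HER2 status from a breast
ultrasound cine loop plus routine clinical covariates:

1. **Tracking** — a per-frame lesion bounding box is obtained (from an
   external detector's boxes, from segmentation masks, or from the built-in
   naive intensity detector), then cleaned by temporal outlier rejection
   and linear interpolation so every frame carries one coherent ROI.
2. **Static features** — 91 radiomics features per frame over the
   rectangular ROI: 19 first-order intensity statistics, 28 local binary
   pattern histogram bins, 44 gray-level co-occurrence features.
3. **Dynamic features** — each static feature traced across frames forms a
   curve; 14 time-domain and 10 frequency-domain (FFT) descriptors per
   curve give 91 × 24 = 2184 features per video.
4. **Modeling** — the dynamic features (standardised, PCA-reduced) feed an
   imaging classifier; the clinical covariates feed a second classifier;
   their probabilities are averaged into the final call. Four base models
   (LR, RF, SVM, XGBoost) are crossed in a 4 × 4 grid and compared.
5. **Evaluation** — AUC, accuracy, sensitivity, specificity and the Youden
   index with percentile-bootstrap 95% CIs, plus a paired
   repeated-resampling comparison across integrated models with paired
   t-tests.

Because clinical video cohorts cannot be redistributed, the package ships a
synthetic cohort generator that plants exactly the statistical structure
the pipeline claims to exploit, making every stage testable end to end.

## The synthetic cohort: what it emulates and what it does not

Each case is a stack of 8-bit grayscale frames containing one elliptical
lesion on a speckled background. Class information enters through three
channels:

- **Echotexture**: the lesion interior sits at a class-specific fractional
  contrast below the background base level (defaults −0.30 for
  HER2-negative, −0.50 for HER2-positive; base level 170, a bright field
  with a hypoechoic mass).
- **Temporal modulation**: the interior mean follows
  m(t) = m₀(1 + a·sin(2π·f·t + φ)) with a = 0.15, a random per-case phase,
  and class frequencies f = 0.05 (negative) vs 0.20 (positive)
  cycles/frame. Frame rate is 1 frame = 1 time unit throughout; no
  physical frame rate is assumed, so all frequencies are cycles/frame.
- **Clinical shift**: covariates are drawn with marginals matched in range
  to a realistic breast-cancer population (age ≈ N(52, 10.6) years, lesion
  size ≈ N(2.37, 1.1) cm, menopause ≈ Bern(0.58), ordinal cN/cT/cTNM from
  population frequencies), with the positive class shifted by +0.4 cm in
  mean size and +0.15 in P(cN ≥ 1).

Speckle is multiplicative gamma noise with unit mean whose shape is set so
that the pixel standard deviation equals `noise_sigma` gray levels
(default 12, about 7% contrast on the background). Setting
`noise_sigma = 0` degenerates exactly to the noiseless closed form, which
the tests exploit. The sinusoidal modulation is a modelling stand-in for
whatever temporal signature distinguishes classes in real cine loops — it
is not a biological claim. The generator also omits attenuation, shadowing,
probe motion, out-of-plane lesion drift and multi-lesion fields, so a
passing end-to-end test demonstrates that the pipeline recovers a planted
spatio-temporal signal, not that it will attain comparable accuracy on
clinical video.

Sample sizes for the shipped end-to-end study follow the published cohort
scale scaled to desk size: 200 cases at 64 frames of 128 × 128 pixels,
split 4:1. The tests use smaller cohorts (16 frames, 48 × 48) where only
structural behaviour is at stake.

## Tracking choices

The ROI is a rectangular box region, inclusive of both boundary pixels and
0-based, matching what a box detector emits; supplied segmentation masks
are reduced to their tight bounding boxes in bypass mode. The naive
detector thresholds each frame 20 gray levels below the frame median
(configurable polarity for hyperechoic lesions), keeps the largest
connected component above 25 px, and reports its box. Rejection flags a
box whose IoU with the element-wise median box of its centered 5-frame
window (missing neighbours skipped, window truncated at the track edges)
falls below 0.3; interpolation then fills rejected/missing frames linearly
per coordinate, copying the nearest observed box into leading/trailing
gaps. The window length, IoU threshold and linear scheme are pragmatic
defaults — cleanup of this kind is standard, but no canonical parameter
set exists; both are exposed as arguments. Cleanup is idempotent and never
alters an observed, unrejected box.

## Static feature design

No canonical itemisation of the 91 features exists, so the registry fixes
one: 19 first-order + 28 LBP + 44 GLCM, the three stated families, summing
to 91. Choices that matter:

- **Quantization**: ROI intensities are binned uniformly into 32 levels
  over a single range computed from *all* ROI pixels of the video, not per
  frame — per-frame ranges would inject artificial temporal variation into
  the feature curves that the dynamic stage would then mistake for signal.
- **GLCM**: symmetric accumulation at distance 1 for the four standard
  directions; 11 Haralick-style statistics each. Both pixels of a pair
  must lie inside the ROI. Degenerate conventions keep every output
  finite: an offset with no valid pair emits zeros, and correlation of a
  zero-variance matrix is 0.
- **LBP**: uniform rotation-invariant codes with bilinear neighbour
  interpolation and tie convention neighbour ≥ center → 1, at (P=8, R=1)
  and (P=16, R=2), giving 10 + 18 normalised histogram bins. Codes are
  computed only where the full square neighbourhood lies inside the mask;
  an ROI too small for any valid center yields an all-zero histogram
  rather than an error.
- **First-order**: population denominators; skewness, kurtosis and CV of a
  constant region are defined as 0; kurtosis is the raw (non-excess)
  standardised fourth moment; entropy/uniformity use a 32-bin histogram.

All three families are checked against independent brute-force oracles
(direct-definition statistics, exhaustive pair enumeration, per-pixel
neighbourhood loops) to 1e-10 relative agreement.

## Dynamic feature design

Only three frequency-domain features are canonical (dc, fc, msf); the
remaining descriptors follow the standard signal-condition-monitoring
feature set so that the counts come out at exactly 14 time-domain and 10
frequency-domain. The spectrum is the one-sided FFT magnitude over bins
k = 1..⌊N/2⌋; bin 0 is reported separately as dc = |X₀|/N and excluded
from the spectral moments, so level and shape information do not mix. No
windowing or detrending is applied before the FFT — the curves are short
(tens of frames) and the planted signal is stationary; a linear detrend
would be the first knob to add for drifting real-world curves. Zero-mass
spectra (constant curves) yield zero moments; zero-denominator shape
factors are 0. Useful identities hold by construction and are tested:
fc, rmsf ∈ [0, 0.5]; msf ≥ fc² (Jensen); Parseval's identity for the
transform wiring; scale equivariance (level features scale, shape
features are invariant).

## Modeling choices

- **Split**: unstratified random split with `round(n · ratio)` training
  cases (ratio 0.8). An explicit `train_size` override exists because
  published splits sometimes round differently (e.g. 357/88 from 445).
- **Imaging branch**: dynamic features are standardised (training mean/sd,
  zero-variance columns dropped), PCA-projected keeping the smallest
  number of components reaching 95% cumulative variance, then classified.
  PCA lives only in the imaging path; the clinical branch has 6
  covariates and needs no reduction.
- **Base models** (documented defaults, not tuned): unpenalised logistic
  regression; random forest, 500 trees; RBF SVM, cost 1, Platt-scaled
  probabilities; XGBoost, 100 rounds, depth 3, learning rate 0.1, single
  thread. All are seeded and deterministic.
- **Fusion**: equal-weight probability averaging
  p = w·p_imaging + (1−w)·p_clinical with w = 0.5 and decision threshold
  τ = 0.5 (ties call positive). Averaging was chosen over stacking for
  transparency: the fused score is auditable back to its branches. Both
  w and τ are arguments.
- **Leakage discipline**: every fitted statistic (scaling, PCA, classifier)
  is a function of training rows only; a test perturbs test rows and
  asserts the fitted artifacts are bit-identical.
- The 4 × 4 grid reports fused and single-branch models on training and
  test cohorts; the winner is the highest test AUC, ties broken by Youden
  index then lexicographic kind names.

## Evaluation choices

AUC is computed in Mann–Whitney rank form (ties count one half) and is
cross-checked against an all-pairs oracle and pROC. Confidence intervals
are percentile bootstrap with B = 1000 case resamples; resamples missing a
class are redrawn up to 10 times. The repeated-resampling comparison draws
m cases *with replacement* per repetition — "m random samples" is
ambiguous between bootstrap and permutation, and with-replacement was
chosen so the repetition distribution reflects sampling variability at the
test-set size; within a repetition all models share the same indices, so
the t-tests are genuinely paired. A model compared with itself differs by
exactly zero in every repetition.

## Numerical conventions and degenerate inputs

Constant regions, single-pixel ROIs, empty spectra, zero denominators and
single-class resamples all have explicit conventions (see above) so that
feature matrices never contain NaN/Inf and evaluation never divides by
zero silently; genuinely undefined quantities (AUC with one class,
sensitivity with no positives) raise errors naming the quantity.

## Problem sizes

The shipped end-to-end study (also run by `scripts/acceptance.R`) uses 200
cases × 64 frames × 128² pixels — about three minutes of feature
extraction on a single core — and the test suite exercises the same
conditions once, with all other tests on miniature cohorts. These sizes
were chosen as the smallest at which the planted class signal and the
resampling machinery behave like the full-scale study.

## Known limitations

- The synthetic generator's temporal signal is sinusoidal; pipelines tuned
  on it may overweight narrowband spectral features relative to what real
  lesion dynamics reward.
- The naive detector assumes one dominant hypo- or hyperechoic lesion and
  is not a substitute for a learned detector on clinical images.
- The feature registry is one defensible itemisation of "91 features";
  other allocations are possible and the registry is config-driven.
- Fusion is probability averaging; stacking or calibrated fusion may do
  better when branch reliabilities differ strongly.
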