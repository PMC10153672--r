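# vidradiomics

Video radiomics for predicting HER2 expression status from breast
ultrasound cine loops.

HER2 status (positive vs negative) steers targeted therapy in breast
cancer, but the reference assays (IHC/FISH) are invasive and sample only
part of a heterogeneous lesion. This package implements a video-based
"deep learning radiomics" pipeline that combines the temporal dynamics of
lesion texture in ultrasound video with routine clinical covariates:

1. **Tracking** — per-frame lesion bounding boxes (from an external
   detector, segmentation masks, or the built-in naive intensity
   detector) are cleaned by temporal outlier rejection (IoU against the
   windowed median box) and coordinate-wise linear interpolation.
2. **Static radiomics** — 91 features per frame over the ROI:
   19 first-order statistics, 28 uniform rotation-invariant LBP histogram
   bins (P=8/R=1 and P=16/R=2), and 44 GLCM features (11 Haralick-style
   statistics × 4 directions at distance 1, 32 gray levels).
3. **Dynamic features** — each static feature traced over frames is a
   curve x(t); per curve, 14 time-domain descriptors (mean, RMS,
   square-root amplitude, crest/impulse/waveform factors, ...) and 10
   FFT-spectrum descriptors — dc = |X₀|/N, center-of-gravity frequency
   fc = Σf·P(f)/ΣP(f), mean-square frequency msf = Σf²·P(f)/ΣP(f), their
   roots, variance frequency, spectral skewness/kurtosis/entropy — giving
   91 × 24 = 2184 features per video.
4. **Two-branch modeling** — imaging branch: standardise, PCA to 95%
   retained variance, base classifier; clinical branch: encoded
   covariates (age, size, menopause, cN, cT, cTNM), base classifier.
   Probabilities fuse as p = w·p_img + (1−w)·p_clin (w = 0.5). Four base
   models (LR, RF, SVM, XGBoost) are crossed in a 4×4 grid.
5. **Evaluation** — AUC (Mann–Whitney form), ACC, SEN, SPC, Youden index
   YI = SEN + SPC − 1, percentile-bootstrap 95% CIs, and a paired
   1000-repetition resampling comparison across models with paired
   t-tests.

Patient videos cannot ship with the package; a synthetic speckle-video
generator plants class-dependent echotexture, temporal modulation
(class frequencies in cycles/frame) and clinical covariate shifts, so the
whole pipeline is testable end to end.

## Worked example

```r
library(vidradiomics)

cfg <- synth_config(
  n_cases = 60, frame_count = 64, frame_shape = c(128, 128),
  temporal_freq = list(negative_class = 0.05, positive_class = 0.20),
  noise_sigma = 12, seed = 11)

res <- run_dlr_study(cfg, imaging_kind = "xgb", clinical_kind = "lr")
pt  <- res$predictions_test
evaluate_predictions(pt$p_fused, pt$label)
#> # A tibble: 1 x 5
#>     auc   acc   sen   spc    yi
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     1     1     1     1     1

glance(res$model)
#> # A tibble: 1 x 7
#>   imaging_kind clinical_kind n_train n_components pca_threshold     w   tau
#>   <chr>        <chr>           <int>        <int>         <dbl> <dbl> <dbl>
#> 1 xgb          lr                 48           36          0.95   0.5   0.5
```

The generator plants a strong, recoverable signal (lesion mean intensity
modulated at 0.05 vs 0.20 cycles/frame by class), so on this synthetic
cohort the fused XGBoost (imaging) + LR (clinical) model separates the
12-case test set perfectly: AUC/ACC/SEN/SPC/YI all 1. The imaging branch
carries nearly all of it — the spectral center-of-gravity of the
lesion-mean trajectory differs by class — while the clinical branch is
weakly informative (covariate shifts of +0.4 cm size and +0.15 in
P(cN ≥ 1)). `run_model_grid()` reports the full 16 fused + 8
single-branch comparison, `bootstrap_ci()` attaches CIs and
`repeated_resample_compare()` reproduces the paired multi-model
comparison; `autoplot()` methods draw the grid heatmap, the resampling
boxplots and ROC curves.

A thin CLI over the same functions lives at `inst/cli/vidradiomics.R`
(subcommands `simulate`, `track`, `features`, `fit`, `evaluate`).

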