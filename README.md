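# waveCanopy

Estimation of crop above-ground biomass (AGB, g/m²) from four-band
(green, red, red-edge, near-infrared) canopy reflectance imagery, fusing
**vegetation indices** with **wavelet texture indices**.

## The problem

Spectral vegetation indices such as NDVI estimate biomass well while a crop
canopy is open, but they saturate once cover closes, and they are nearly
blind to vertically growing organs such as rice panicles. The spatial
*texture* of the canopy image keeps changing after the spectral signal
flattens: panicle emergence raises local contrast, which shows up in the
high-frequency subbands of a wavelet decomposition. waveCanopy implements a
pipeline that quantifies both signals and fuses them:

1. **Wavelet textures (WTs).** Each per-plot image patch is decomposed per
   band with a single-level orthonormal 2-D Haar transform into the
   approximation subband LL and detail subbands LH, HL, HH. Four statistics
   are computed per subband — mean, population variance, energy (mean
   square) and an entropy measure −(1/MN)·Σ q·log₂ q on q = |coefficient| —
   giving 4 bands × 4 subbands × 4 statistics = **64 features** named like
   `LL_Red_Mea` or `HH_Red-edge_Ent`.
2. **Normalized-difference wavelet texture indices (NDWTI).** After
   per-feature min–max scaling (fitted on the training partition),
   `NDWTI(WT1, WT2) = (WT1 − WT2) / (WT1 + WT2)` is built for **all 4032
   ordered pairs** (2256 high–high, 240 low–low, 1536 mixed) per growth
   stage.
3. **Screening.** Features are ranked per stage by |Spearman ρ| against
   AGB (Shapiro–Wilk normality reports justify the rank correlation); the
   top 5 vegetation indices and top 5 NDWTIs (reversed pairs deduplicated)
   become model inputs.
4. **Models.** Per stage (pre-heading, post-heading, all-stage; 75/25
   stage-wise splits) and per feature set (VIs, NDWTIs, VIs+NDWTIs):
   univariate regression, multiple linear regression, and a random forest
   tuned by a tree-structured Parzen estimator over
   n_estimators/max_features/max_depth/min_samples_split/min_samples_leaf
   with 10-fold cross-validated R² as the objective. Metrics are
   R² = 1 − SSres/SStot and RMSE (g/m²).
5. **Interpretation.** Exact interventional Shapley attributions of the
   tuned forest (local accuracy: base value + Σ attributions = prediction),
   with Z-score standardization and mean-|value| importance ranking.

A **synthetic canopy-scene generator** emulates the statistical structure
the method relies on — canopy cover saturating in AGB, soil pixels with
NIR ≈ red, stage-dependent spectral saturation, and panicle-like speckle
post-heading — so the whole pipeline is testable without field data.

## Worked example

```r
library(waveCanopy)

samples <- c(generateDataset(sceneConfig("pre_heading",  seed = 101L), n = 90),
             generateDataset(sceneConfig("post_heading", seed = 102L), n = 54))
res <- runPipeline(samples, rfTrials = 20L, seed = 7L)

subset(res$metrics, partition == "test" & grepl("^rf", model))[, 1:4]
```

```
        stage         model partition        r2
  pre_heading        rf_VIs      test 0.9085233
  pre_heading     rf_NDWTIs      test 0.9195714
  pre_heading rf_VIs+NDWTIs      test 0.9242075
 post_heading        rf_VIs      test 0.3244247
 post_heading     rf_NDWTIs      test 0.4973787
 post_heading rf_VIs+NDWTIs      test 0.4945267
    all_stage        rf_VIs      test 0.6848019
    all_stage     rf_NDWTIs      test 0.7024102
    all_stage rf_VIs+NDWTIs      test 0.6979784
```

Each row is the held-out R² of a tuned forest for one growth stage and one
feature set. The pattern the method predicts is visible at this small
demonstration scale (144 samples; the test suite runs the same comparison
at 500): post-heading the spectral-only model degrades sharply — the
canopy is saturated and panicles are nearly invisible to the indices —
while texture indices retain much more of the signal, and the fused and
per-family forests are close at the remaining stages.

```r
head(res$stages$post_heading$importance, 3)
#                          feature mean_abs_shap rank
# 1 NDWTI(LL_Green_Var-LL_Red_Ene)     152.10982    1
# 2 NDWTI(HL_Green_Var-LL_Red_Ent)      21.89991    2
# 3 NDWTI(HL_Green_Ene-LL_Red_Ent)      17.67201    3
```

Post-heading, texture indices head the Shapley importance ranking.

`runPipeline(..., outDir = "out")` additionally writes the flat artifacts:
`features.csv` (21 VI + 64 WT columns per sample), per-stage correlation
reports, `selection.yaml`, `metrics.csv`, per-stage Shapley matrices and a
`manifest.yaml` recording the seed. A thin command-line front-end is
installed at `inst/scripts/agb-pipeline.R`.

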