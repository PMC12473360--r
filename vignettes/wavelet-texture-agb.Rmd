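---
title: "Wavelet-texture-fused biomass estimation: models, parameters and design notes"
author: "waveCanopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-texture-fused biomass estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveCanopy)
```

# The estimation problem

Above-ground biomass (AGB, g/m²) of a crop such as paddy rice is the
reference quantity for growth monitoring, but measuring it means cutting,
drying and weighing quadrat samples (`agbFromSampleWeight()` converts a
quadrat dry weight to g/m², conventionally over a 0.25 m² area). Multiband
canopy imagery offers a non-destructive proxy. Two kinds of image-derived
predictors behave very differently over a season:

* **Vegetation indices (VIs)** — algebraic combinations of the per-plot
  band-mean reflectances (green, red, red-edge, NIR). They respond to
  pigment absorption and canopy cover, but once cover closes the red/NIR
  contrast saturates, and reproductive organs (panicles) that accumulate
  much of the late-season biomass barely change them.
* **Wavelet textures (WTs)** — statistics of the subbands of a
  single-level 2-D Haar decomposition of the plot patch. The approximation
  subband (LL) carries overall brightness/structure; the detail subbands
  (LH, HL, HH) respond to local contrast, which rises when panicles
  emerge and the canopy surface roughens.

The package's central construction is the **normalized-difference wavelet
texture index**, `NDWTI = (WT1 − WT2) / (WT1 + WT2)` on min–max-scaled
texture features: the same functional form as NDVI, applied to pairs of
texture statistics so that common scale and illumination effects cancel.

# Pipeline and assumptions

`runPipeline()` executes, per growth stage (pre-heading, post-heading, and
their union "all-stage"):

1. feature assembly (`assembleFeatures()`): 21 VIs from band means plus
   the 64 WT features (4 bands × 4 subbands × 4 statistics);
2. stage-wise 75/25 random split (`splitStagewise()`), the all-stage
   partitions being the unions of the per-stage partitions so no sample
   changes sides;
3. min–max scaling of the WT features fitted on the training partition,
   then NDWTI construction over all 4032 ordered pairs (`ndwtiTable()`);
4. screening by |Spearman ρ| against AGB on the training partition
   (`rankFeatures()`), keeping the top 5 VIs and the top 5 NDWTIs after
   collapsing a pair with its reversal (`selectTopK(dedup = TRUE)` —
   antisymmetry makes their |ρ| identical);
5. three models per feature set (VIs, NDWTIs, fused): univariate least
   squares, multiple linear regression, and a tuned random forest;
6. exact Shapley attributions of the fused forest.

The statistical assumptions are mild and explicit: AGB relates
*monotonically* (not linearly) to the screened features, which is why
screening uses Spearman rather than Pearson correlation — Shapiro–Wilk
reports (`shapiroWilk()`) typically reject normality for
reflectance-derived features, and the rank correlation is unaffected. No
multiple-testing correction is applied across the 4032 screening
correlations: selection is by effect size, not significance, and the
reported ρ values of selected features are therefore optimistically biased
(winner's curse); treat them as a ranking device, not as inference.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `trainFraction` | 0.75 | — | conventional 75/25 split; train size is round-half-up |
| `k` (features/family) | 5 | — | balances stage specificity against model complexity |
| `cvFolds` | 10 | — | standard k-fold compromise at a few hundred samples |
| `rfTrials` | 100 (spec), 20 (pipeline) | trials | 20 suffices for the 6-dimensional space at desk scale |
| `n_estimators` | 50–500 | trees | search range |
| `max_depth` | 3–30 | levels | search range |
| `min_samples_split` | 2–10 | samples | search range |
| `min_samples_leaf` | 1–10 | samples | search range |
| `max_features` | sqrt / log2 / 0.3–1.0 | fraction | mixed categorical + fraction |

All forest inputs are z-score standardized with training-partition moments
before fitting; forests are scale-equivariant, but standardization keeps
hyperparameter behaviour comparable across feature sets and stages.

## The hyperparameter search

No installed R package provides a tree-structured Parzen estimator, so the
sequential search is implemented in-package (`fitRfTuned()`): 10 random
startup trials, then adaptive proposals. Observed trials are split at the
top-25% quantile of the cross-validated R² objective into "good" and
"bad"; each numeric hyperparameter gets 1-D Gaussian kernel densities
l(x) (good) and g(x) (bad) with a rule-of-thumb bandwidth floored at 1/50
of the range, the categorical `max_features` mode gets Laplace-smoothed
frequencies, and of 24 candidates drawn from l the one maximizing
Σ log l − log g is evaluated next. The whole search is a deterministic
function of the spec seed (single-threaded forests, per-trial derived
seeds).

# What the synthetic generator emulates — and what it does not

`sceneConfig()` / `generateDataset()` produce four-band patches whose
structure mirrors the field situation the method targets:

* **Cover link.** Canopy cover is `1 − exp(−coverageGain · AGB)`:
  monotone, saturating, two-parameter. Pre-heading defaults (gain 8e-4
  over AGB 185–1615 g/m²) traverse cover 0.14–0.72; post-heading defaults
  (2e-3 over 633–1947 g/m²) sit at 0.72–0.98, i.e. in the saturated
  regime where spectral indices flatten.
* **Spectra.** Fixed end-members (canopy NIR 0.45 / red 0.05; soil NIR
  0.20 / red 0.18 — soil close to the bare-soil line) mixed per pixel by a
  spatially smooth weight field whose pointwise mean equals the cover
  fraction exactly. A per-sample lognormal jitter (sd 0.04) on the canopy
  spectrum emulates plot-to-plot pigment variation and decorrelates the
  spectral from the textural information channel.
* **Texture.** The mixing field is a 9×9-box-smoothed Gaussian field, so
  canopy/soil transitions are predominantly low-frequency and the detail
  subbands of speckle-free patches stay near the sensor-noise floor.
  Post-heading, `rpois(speckleDensity · AGB)` bright 2×2 blobs (+0.15
  reflectance in all bands) emulate emerged panicles: biomass raises
  high-frequency texture exactly where it stops raising NDVI.
* **Noise.** Additive Gaussian, sd 0.01 reflectance, truncated at zero —
  simplicity over sensor realism.
* **Scale.** The default 32 px patch corresponds to a 0.5 m quadrat at
  roughly 1.5 cm ground sampling distance from a low-altitude multispectral
  platform; the 3×6 plot grid mirrors a typical 18-plot nitrogen×variety
  trial.

Not emulated: radiative transfer (no multiple scattering, no
view/sun-angle effects), 3-D canopy geometry, band misregistration,
orthomosaicking artifacts, and spatial autocorrelation *between* plots.
Consequently, a passing test suite shows the pipeline recovers the
designed monotone spectral and textural links under saturation and noise;
it does not certify accuracy on real UAV imagery, where calibration and
structural effects dominate the error budget.

# Numerical choices

* **Haar convention.** Orthonormal filters (h = [1,1]/√2, g = [1,−1]/√2),
  chosen for the exactly testable Parseval property (energy conserved to
  1e-9 relative on random patches). LH is row-lowpass/column-highpass
  (horizontal detail), HL its transpose. Odd dimensions are padded by
  half-sample symmetric replication of the last row/column; energy
  conservation then holds with respect to the padded patch. Unnormalized
  Haar variants rescale subbands by constants; after min–max scaling the
  downstream indices are unchanged, so only the orthonormal form is
  offered.
* **Entropy convention.** The subband entropy is
  −(1/MN)·Σ q·log₂ q with q = |coefficient| and 0·log₂ 0 := 0. Detail
  coefficients are signed and frequently zero, so a direct logarithm is
  undefined on them; the absolute-value reading preserves the functional
  form while being defined everywhere. This is a defined stand-in for an
  underspecified convention, and is documented as such.
* **Variance.** Population form (divisor MN), making
  `Ene − Mea² = Var` an exact identity that the suite asserts at 1e-9.
* **Guards.** VI formulas are evaluated with a guarded division
  (|denominator| < 1e-9 → `NA` sentinel, never ±Inf); NDWTI returns the
  symmetric limit 0 when |WT1 + WT2| < 1e-12 (both features at their
  training minimum); min–max scaling maps constant training columns to 0;
  constant features yield an `NA` Spearman and are dropped from screening
  with a warning.
* **Tie-breaks.** Equal |ρ| is resolved lexicographically, and of a
  reversed NDWTI pair the lexicographically smaller name is kept, so
  selection is stable across runs and platforms.
* **Split rounding.** Train size is ⌊0.75·n + 0.5⌋ (round half up):
  468 → 351/117 and 234 → 176/58.
* **Rank deficiency.** `fitMlr()` answers a rank-deficient design with a
  warning and the minimum-norm (pseudoinverse) solution rather than
  silently dropped columns — near-collinear NDWTI selections at small n
  make this path reachable.
* **Shapley.** Interventional value function v(S) = mean over background
  rows of f(x_S, b_∖S). Up to 15 features, all 2^p coalitions are
  enumerated and weighted exactly; beyond that, seeded permutation
  sampling with a uniform recentring of the telescoping residual. Both
  routes satisfy local accuracy (base + Σ attributions = prediction)
  exactly, which the suite checks at 1e-6 relative. Z-scoring of
  attributions uses population standard deviations.
* **Raster storage.** Multiband TIFF with 32-bit channels; roundtrips are
  exact to storage quantization (~2e-10 absolute), not bit-exact in
  doubles.

# Open design decisions

* **"Simple regression"** is univariate ordinary least squares with an
  optional quadratic flag — the simplest defensible reading; the flag
  preserves flexibility for saturating relationships.
* **Scaler scope.** Min–max parameters are fitted on the training
  partition only and applied unclipped to test data. Pooled fitting would
  leak test information into the index construction; train-only is
  standard practice and costs at most values slightly outside [0, 1].
* **Ordered pairs.** Both directions of every pair are enumerated (4032 =
  64·63), reproducing the published combinatorics; the redundancy (a
  reversal is the negation) is removed only at selection time.
* **CV objective** is mean fold R²; R² is the headline metric of the
  method, and the fold mean is the conventional estimator.

# Problem sizes used by the test suite

The suite exercises the full pipeline at 500 samples (333 pre-heading +
167 post-heading, patch 32 px) with a reduced 20-trial search — the scale
at which the stage-wise fusion behaviour is assessed, with the fusion
margin averaged over five fixed seeds because tuned forests on partially
redundant feature sets produce near-ties that wobble a few hundredths from
seed to seed. Unit tests use patches of 8–32 px and sample counts of
10–200. `scripts/acceptance.R` re-runs the pipeline at 468 + 234 samples,
matching the split arithmetic it reports.

# Known limitations

* The 21-entry index registry covers the standard four-band indices; any
  site-specific variant must be supplied via the registry CSV.
* Spearman screening at 4032 candidates without error control means
  selected-feature correlations are biased upward; models are validated on
  held-out data, which is where accuracy claims should be read.
* The forest cannot extrapolate beyond the training AGB range
  (tree-ensemble averaging bound); late-season biomass above anything seen
  in training is systematically underpredicted.
* Shapley attributions explain the fitted model, not the crop: a feature's
  attribution rank reflects what the forest uses, which under redundancy
  (highly correlated NDWTIs) can concentrate on an arbitrary
  representative of a correlated group.
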