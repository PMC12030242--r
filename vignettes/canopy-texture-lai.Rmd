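---
title: "Estimating leaf area index from multispectral canopy texture"
author: "canopyLAI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf area index from multispectral canopy texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyLAI)
```

## The problem

Leaf area index (LAI, one-sided leaf area per unit ground area,
cm² cm⁻²) is the standard descriptor of crop canopy development, and
estimating it from UAV-borne multispectral imagery is a core task in
field phenotyping. Spectral vegetation indices (VIs) computed from
plot-mean reflectance saturate in dense canopies; image *texture* —
the spatial organization of gray levels within the plot — carries
complementary structural information. This package implements a full
texture-augmented LAI estimation pipeline for six-band canopy imagery
(blue 450 nm, green 555 nm, red 660 nm, red-edge 720/750 nm,
near-infrared 840 nm; see `msBandInfo()`):

1. plot-level preprocessing: vegetation masking and mean reflectance
   (`vegetationMask()`, `plotMeanReflectance()`);
2. ten classical VIs (`computeVIs()`);
3. 48 gray-level co-occurrence matrix (GLCM) texture features — eight
   statistics per band (`plotTextureFeatures()`);
4. eleven algebraic texture-index families combining two or three
   texture features, each optimized by exhaustive correlation search
   against LAI (`searchFamily()`, `bestCombinationTable()`);
5. significance screening of candidate predictors
   (`screenVariables()`);
6. a 15-input-combination × 3-model estimation grid (`runGrid()`) and
   per-pixel LAI inversion maps (`predictMap()`).

Because no public plot imagery accompanies the study design this
package emulates, a first-class synthetic scene generator
(`generateExperiment()`) renders treatment-structured plot rasters in
which both reflectance and texture are driven by a latent LAI, so every
stage of the pipeline is testable end to end.

## GLCM texture model

Each band is quantized to `G = 32` gray levels by min–max scaling over
the masked pixels and flooring into bins (a constant band maps to level
0). For every pixel whose centered `7 × 7` window lies fully inside the
raster and whose center is vegetation-masked, the co-occurrence matrix
counts pairs of quantized levels at offset `(dx, dy) = (1, 1)` —
pixel `(r, c)` against `(r + 1, c + 1)` — within the window, adds the
transposed counts (symmetric GLCM, standard Haralick practice that
stabilizes the correlation statistic on 36-pair windows), and
normalizes to probabilities `P(i, j)`. Gray levels enter the statistics
as the integers `0 … G − 1`. Eight statistics are computed per window
and averaged over windows:

* MEA `= Σ i P(i,j)` and VAR `= Σ (i − u)² P(i,j)` (marginal mean and
  variance),
* HOM `= Σ P/(1 + (i−j)²)`, CON `= Σ (i−j)² P`, DIS `= Σ |i−j| P`,
* ENT `= −Σ P log P` (natural log, `0·log 0 = 0`; the sign is chosen so
  entropy is nonnegative and increases with disorder),
* SEM `= Σ P²`,
* COR `= Σ (i−μᵢ)(j−μⱼ) P / √(VARᵢ · VARⱼ)`, defined as 0 when either
  marginal variance vanishes so it stays in `[−1, 1]`.

The 48 features are labeled feature-plus-band, e.g. `DIS5` is the
dissimilarity of band 5 (750 nm red edge). Window size 7, unit offsets,
and all-six-band extraction are the package defaults and propagate end
to end. `G = 32` balances gray-level resolution against the sparsity of
a 7 × 7 window (36 ordered pairs); window placement uses full windows
only (no border padding), and aggregation is an unweighted mean over
masked centers.

## Vegetation and texture indices

The ten VIs (SAVI, EVI, MSR, DVI, CIgreen, RDVI, TVI, GNDVI, VDVI,
CVI) are computed from plot-mean reflectance (means first, then the
index; a per-pixel alternative is available through
`predictMap()`-style window means). TVI is implemented with the
radical, `√(NDVI + 0.5)`, and GNDVI as `(NIR − G)/(NIR + G)` — the
standard forms. CVI is `(2NIR − R − G)/(2NIR + R + G)` here, which
differs from some uses of that acronym elsewhere; the definition above
is the one this package follows.

Texture indices combine two features (`RTI = Ti/Tj`, `DTI = Ti − Tj`,
`ATI = Ti + Tj`, `NDTI = (Ti − Tj)/(Ti + Tj)`, `RDTI = 1/Ti − 1/Tj`,
`RATI = 1/Ti + 1/Tj`) or three (`RTTI = Ti/Tj/Tk`,
`DTTI = Ti − Tj − Tk`, `NDTTI = (Ti − Tj − Tk)/(Ti + Tj + Tk)`,
`RDTTI = 1/Ti − 1/Tj − 1/Tk`, `RATTI = 1/Ti + 1/Tj + 1/Tk`). The search
evaluates every *ordered* tuple with repetition allowed — 48² pair and
48³ triple cells per family — because several families are asymmetric
in their arguments and reported optima elsewhere repeat labels. For
each tuple, samples with non-finite index values (division by zero in
the reciprocal and normalized families) are dropped; a tuple is invalid
if fewer than 80% of samples survive or if either variable is
numerically constant (population variance ≤ 1e−12). The search
maximizes |r| (families can be anti-correlated with LAI) but reports
the signed correlation; exact ties resolve to the lexicographically
first tuple for reproducibility. Screening uses the raw two-sided
p < 0.05 of the Pearson t-test, without multiplicity adjustment — a
deliberate mirror of common practice that inflates selection under the
null; treat screened sets accordingly.

## Estimation grid

The four input blocks are the screened VIs, the screened TFs, the six
best two-feature index columns (TIs) and the five best three-feature
index columns (TTIs); all 15 non-empty block subsets are crossed with
three estimators on one shared random 2/3–1/3 modeling/validation
split:

* **SVM** — ε-regression, polynomial kernel, `C = 20`,
  `gamma = 0.02`; the polynomial degree is not pinned by the emulated
  protocol, so the library-conventional degree 3 is the default and
  exposed in `modelSpec()`.
* **PLSR** — latent variables grown while each added component raises
  the cumulative explained Y-variance by ≥ 5 percentage points, capped
  at `min(10, column rank, n − 2)`. The explained-variance curve is
  computed from training-set predictions at each component count (a
  deterministic operationalization of the rule; cross-validated
  variants would add split noise without changing the selection in the
  regimes exercised here).
* **XGBoost** — 100 trees, learning rate 0.03, maximum depth 5,
  single-threaded for determinism.

Features are standardized for SVM and PLSR with center/scale fitted on
the modeling set only (the test suite asserts that a leaky scaler would
change the predictions); zero-variance and exactly duplicated columns
are dropped at fit time. Validation metrics are `R² = 1 − SSres/SStot`
(the determination coefficient on predictions, which penalizes bias,
not squared Pearson), RMSE (cm² cm⁻²), and mean relative error
`MRE = (100/n) Σ |y − ŷ|/y` (%).

`predictMap()` inverts a trained model per pixel: VIs from the 7 × 7
window-mean reflectance, texture features from the window GLCMs, and
index columns from the training-time best tuples; pixels outside the
mask or without a full window are no-data. Window-level feature
distributions differ from plot-level ones (a window sees 36 pairs, a
plot thousands), so maps are interpreted relatively; the tests assert
rank agreement between map means and plot-level predictions rather
than a fixed absolute tolerance.

## The synthetic experiment

`generateExperiment()` emulates a two-season split-plot field trial:
3 mulching methods (none, straw, plastic film) × 5 nitrogen rates
(0–280 kg ha⁻¹) × 3 replicates × 2 seasons = 90 plots of 48 × 48
pixels. The latent LAI is additive:

```
LAI = base + mulch effect + nitrogen response + season offset + plot noise
```

with a saturating nitrogen dose–response
`gain · (1 − e^(−N/100)) − 0.0015 · max(0, N − 210)` that peaks at
210 kg ha⁻¹, a shared N(0, 0.2) season offset, N(0, 0.25) plot noise,
and truncation at 0.05 to keep relative errors finite. The defaults
place the expected LAI of the film-mulch + 210 kg N treatment at 2.97
and span roughly 0.3–3.6 across treatments — the canopy range of a
bolting-stage oilseed rape stand.

Scenes follow a statistical radiative model, not physical radiative
transfer: mean canopy reflectance per band is the Beer–Lambert-style
mixture `μ_b(L) = soil_b + (leaf_b − soil_b)(1 − e^(−k_b L))`, which
reproduces the red-decrease/NIR-increase contrast and VI saturation;
canopy cover is `1 − e^(−0.8 L)` realized by thresholding a correlated
Gaussian field; canopy pixels fluctuate around `μ_b` with an
LAI-dependent texture SD (0.01 rising toward 0.03–0.06 per band); all
fields are white noise smoothed with a Gaussian kernel of σ = 2 px and
re-standardized. Two nuisance terms decouple the information channels
so that fusing spectra and texture genuinely helps: a per-plot,
per-band lognormal jitter (sd 0.10) of the leaf asymptote limits VI–LAI
correlations to roughly the 0.6–0.9 range, and a per-plot lognormal
jitter (sd 0.15) of the texture amplitude keeps texture informative but
imperfect. These scales were fixed once, from the correlation ranges
reported for comparable field data, before the recovery properties were
tested.

What the generator does **not** emulate: illumination and view-angle
effects, mixed soil–vegetation pixels, georeferencing error,
row-structure and lodging, between-band noise correlation, and real
GLCM anisotropy. Passing recovery tests therefore demonstrate that the
pipeline's machinery is correct and that its comparative behavior
(texture fusion helping, three-feature indices beating two-feature
ones) emerges under controlled signal — not that the same accuracies
would be attained on field imagery.

## Numerical and design choices

* Quantization is min–max over masked pixels; windows reuse the plot's
  affine map, so band-wise constant offsets cancel exactly.
* Degenerate co-occurrence marginals (COR), empty ROIs, sub-window
  scenes, constant targets, and all-invalid search tuples raise typed
  errors or flagged values rather than propagating NaN.
* Determinism: every stochastic step takes an explicit seed; per-plot
  seeds are derived arithmetically from the run seed (kept below 2³¹),
  and RNG state is saved/restored around draws, so a run is a pure
  function of (configuration, seed) and CSV artifacts are
  byte-reproducible.
* Storage: multi-page 32-bit float TIFF per plot with a JSON band
  sidecar, 8-bit TIFF masks, CSV tables; the inversion map is written
  as LAI/10 in a float TIFF with 0 as no-data.
* Problem sizes in the shipped tests: 90-plot default runs for the
  integration properties, 20 generator seeds for the stochastic
  ordering properties, ≤ 12 × 12 images for brute-force oracle
  equivalence, 10⁴ draws for the treatment-mean check.

## Limitations

* Screening is unadjusted for multiplicity by design (documented
  above).
* The exhaustive search is O(K²)/O(K³) per family; at K = 48 this is
  ~5.5 × 10⁵ correlations per three-feature family and runs in seconds
  in compiled code, but larger alphabets would need pruning.
* ENVI-style implementations quantize and normalize windows in
  unspecified ways; exact numeric parity with any particular GUI tool
  is not claimed — the contracts here are the formulas above, enforced
  against brute-force oracles.
* Single-split validation mirrors the emulated protocol; repeated
  splits would tighten the grid's metric estimates.
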