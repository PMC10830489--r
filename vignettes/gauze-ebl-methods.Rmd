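---
title: "Estimating intraoperative blood loss from gauze images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intraoperative blood loss from gauze images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Intraoperative estimated blood loss (EBL) is routinely obtained by weighing
blood-soaked gauze by hand. `gauzeloss` implements an automated image-based
alternative for laparoscopic surgery: detect gauze in the camera frame,
summarise how crumpled the fabric looks, and regress the absorbed blood mass
in grams from the masked gauze image together with texture features. This
vignette documents the models, the assumptions behind them, the synthetic data
the package ships instead of clinical images, and the numerical choices a
careful reader or maintainer would ask about.

## Pipeline overview

A frame passes through two stages.

**Detection.** The frame is cut into square tiles (64 px by default) and each
tile is classified into one of four states: background tissue, clean gauze,
stained gauze, or soaked gauze. A pixel belongs to the gauze mask when the
mean gauze probability (clean + stained + soaked) of the tiles covering it is
at least 0.5; morphological closing with a 5 px disc removes tile-boundary
artifacts. The masked gauze image (frame with non-gauze pixels zeroed) and the
gauze patches (tiles with at least 50% mask coverage) feed the second stage.
Tiles not covered by any full tile at the frame border count as background —
an explicit edge convention rather than an accident of indexing.

**Regression.** Three variants of the EBL regressor are implemented, which is
exactly the comparison the package exists to support:

* *base* — a convolutional backbone embeds the masked gauze image; a fully
  connected head with linear activation outputs grams.
* *CS* — the crumpled state value (CSV) of the whole gauze region passes
  through a small MLP whose output is concatenated with the image embedding.
* *P-W CS* — instead of one scalar, the per-patch CSVs, each weighted by the
  patch's blood evidence, form a fixed-length vector input to the MLP.

The premise linking texture to mass is physical: wet, blood-heavy gauze
drapes and folds differently, and folds concentrate where blood is absorbed,
so local texture variation carries information about mass that a
coarsely-downsampled colour image loses.

## The crumpled state value

For a grayscale image (luminance 0.299R + 0.587G + 0.114B), the local binary
pattern (LBP) code of a pixel thresholds `p = 8` neighbours sampled on a
circle of radius `r = 3` against the centre intensity: bit *k* is 1 when
`g_k − g_c ≥ 0` (a tie counts as 1), and the bits are read as an integer in
[0, 255]. Neighbour *k* sits at angle `2πk/p`, starting at the offset
`(+r, 0)` in (column, row) and proceeding counterclockwise. The CSV is the
mean LBP code over the detected gauze region — the sum of gauze LBP codes
divided by the pixel count of the region.

Choices the definition leaves open, and what this package does:

* **Interpolation.** Non-integer neighbour positions are resolved by bilinear
  interpolation (standard for circular LBP); a nearest-pixel mode exists so
  tests can use exact integer oracles. Comparisons use an epsilon of 1e-6
  gray levels so interpolation round-off cannot flip a tie on constant
  regions (a constant image must code to 255 everywhere).
* **Borders.** Pixels whose sampling circle leaves the image are marked
  invalid and excluded from both the numerator and the denominator of the
  CSV. Edge replication was rejected because it biases codes exactly where
  the mask boundary is.
* **Masking order.** Codes are computed on the original grayscale frame and
  only the *summation* is restricted to the mask, so background pixels can
  appear in a boundary pixel's neighbourhood; computing codes on the zeroed
  masked image would instead manufacture spurious edges.
* **Patch weighting.** The per-patch weight standing in for "the blood in
  that patch" is the detector's stained + soaked probability — the only
  signal available at inference time. Two further modes exist: `uniform`
  (weights 1, for ablation) and `ground_truth_mass` (simulation only, to
  validate the proxy against the true per-patch mass). The weighted CSVs are
  sorted descending and zero-padded to length 16; sorting makes the vector
  invariant to patch enumeration order, and 16 covers the patch counts that
  realistic gauze areas produce at 64 px tiles.

## The regression networks

No deep-learning framework is available to this package's target
environment, so it carries its own small, fully deterministic neural-network
engine: 3×3 same-padding convolutions (computed as nine shifted matrix
multiplies in BLAS), mean pooling, dense layers, ReLU/swish activations,
Adam, and MAE/MSE/cross-entropy losses. Backpropagation is verified against
numerical differentiation in the test suite. The default backbone
(`small_cnn`: three conv blocks of widths 8/16/32, global mean pooling) is
sized for CPU-minute training; `vgg16_style`, `googlenet_style` and
`efficientnet_b3/b5_style` settings scale width and depth (the
EfficientNet-style stacks use swish activations) but are architectural
gestures, not reproductions, and no pretrained weights exist or are shipped.

Training defaults follow the published comparison setup: batch size 32,
learning rate 5e-3, MAE loss, linear head activation. Two stabilisers are
layered on top for short CPU runs: the learning rate steps down (×0.5 after
60% and ×0.25 after 85% of the epochs) and gradients are clipped to a global
L2 norm of 5 — MAE gradients are sign-valued, and Adam at 5e-3 otherwise
spikes on small batches. The masked image is cropped to the mask's bounding
box, zero-padded square, and resized to 64 px (a deliberate desk-scale
choice; the classical 224 px input costs ~12× more per step and adds nothing
at 256 px frame resolution). CSV features are standardised by
training-split mean/sd (per sorted position for the patch vector) and
clipped to ±5 standard deviations, so a feature configuration unseen in
training cannot drive the head into extrapolation; images are
channel-normalised the same way; all constants are stored in the fit. The
best validation-loss epoch's weights are retained, and predictions are
clamped at 0 g on output.

## The synthetic scene generator

Clinical gauze images are not redistributable, so the generator is a
first-class module whose defaults *are* the study conditions everywhere in
the package:

* **Blood mass** ~ Gamma(2.2, scale 1.9) truncated to [0.13, 9.98] g — a
  right-skewed distribution with mean ≈ 4.17 g matching weighed surgical
  gauze.
* **Frames** are 256×256 by default (full HD is available via
  configuration); the gauze is a single star-convex region covering 25–45%
  of the frame. Taut cloth is rendered as flat intensity plateaus crossed by
  darker thread lines (period 11 px): uniform reflectance produces exact
  intensity ties, which the LBP tie convention (s(0) = 1) reads as high
  codes, so flat gauze sits near CSV ≈ 177.
* **Crumpling** erodes those ties progressively: the weave is warped along
  the gradient of band-limited noise (nearest-neighbour resampling, no
  interpolation blur), fold valleys darken in quantised shadow tiers whose
  level-set edges multiply with intensity, and micro-wrinkle grain touches a
  pixel fraction growing with intensity. The CSV consequently falls from
  ≈ 177 (flat) towards ≈ 127 (heavily crumpled) — a wide, monotone response
  — and windowed variance inside the mask is non-decreasing in the crumple
  amplitude; the tests assert both. Crumple intensity is coupled to mass
  (`0.35 + 0.22·mass + noise`), encoding the premise that heavier gauze is
  more crumpled.
* **Stain** seeds are drawn inside the mask with probability increasing in
  the local fold amplitude (blood and crumple co-locate); each seed
  contributes a Gaussian stain kernel, the per-pixel mass map is normalised
  to sum exactly to the label, and the seed pool is nested so the stained
  footprint grows monotonically with mass at a fixed seed. Three properties
  make colour alone under-determine mass: the footprint *saturates* as the
  gauze approaches soaked (beyond a few grams extra blood deepens rather
  than spreads the stain), a per-scene darkness factor and a lognormal
  absorption factor add nuisance spread, and stains render as flat tiers
  with a sharp boundary (as blood dries into rings) so the cloth's texture
  ties survive inside each ring. This is what makes the crumple features
  genuinely informative in the model comparison — in the saturated regime
  only the crumpled state still discriminates heavy gauze — rather than
  redundant with the image.
* **Tile datasets** for detector training are cut from rendered scenes and
  labelled by ground truth, keeping only clearly-background (≤20% gauze
  coverage) or clearly-gauze (≥80%) tiles, with roughly 2.75× as many
  background as per-state gauze tiles — mirroring the balance of curated
  laparoscopic tile collections.

What the generator does **not** model: specular highlights, smoke, motion
blur, instruments occluding gauze, photorealistic blood rheology. Passing
tests on this data therefore demonstrate that the pipeline's machinery is
correct and that the comparison protocol can detect the value of crumple
features when the generative premise holds — not that the shipped defaults
would reach any particular accuracy on clinical video.

## Evaluation protocol

MAE (g), MAPE (%) and MSE (g²) follow their textbook definitions; MAPE
refuses true values below 0.01 g with an explicit error naming the offending
gauzes (real weighed gauze never goes below 0.13 g, so the guard only fires
on malformed input). Reports are stratified by true EBL (≤3 g, 3–5 g, >5 g by
default). The overall row pools all samples; because a stratum-mean differs
on imbalanced strata, `overall = "both"` emits both and the pooled row is
the default. Per-patient evaluation sums predicted and true masses within a
patient before computing errors, and summarises agreement with a
Bland–Altman analysis (differences are predicted − true; limits of agreement
are bias ± 1.96 sd). Cross-validation is grouped by patient — no patient
spans folds — and stratified by mean patient EBL via round-robin assignment.

Problem sizes used by the shipped checks (chosen once, as the package's own
desk-scale study conditions): roughly 1,000 tiles (550 background) and 20
epochs for the detection study; 300 gauzes, a 3:1:1 EBL-stratified split and
35 epochs for the three-variant comparison (the patch-vector branch
converges more slowly than the scalar-CSV branch, so the comparison trains
all variants to the longer schedule); 20–40 fresh frames for end-to-end
pipeline runs. Training a small network on a few hundred samples
for a handful of epochs is intrinsically noisy: the P-W CS variant in
particular can land well away from its typical error on an unlucky
data/seed combination, which is why the shipped comparisons average over
training seeds.

One train/serve consistency rule deserves emphasis: the deployed regressor
must be trained on features produced by the *same* detector it will run
behind. Detector masks are tile-quantised and morphologically closed, so
they differ subtly from the simulation's smooth ground-truth masks;
training on ground-truth features and serving on detector features is a
measurable domain shift on synthetic data, even with a near-perfect
detector. `regression_features()` therefore accepts the detector as an
argument, and the end-to-end runs train the deployed model through it.

## Worked example

```{r}
library(gauzeloss)

tiles <- generate_tile_dataset(200, seed = 1)
detector <- train_tile_classifier(tiles, train_config = list(epochs = 20))
glance(detector)

ss <- generate_scene_set(300, seed = 11)
feats <- regression_features(ss$scenes)
feats$split <- stratified_split(feats$ebl_g, c(3, 1, 1), 11)

fit <- train_regressor(regression_config(variant = "pwcs", epochs = 25), feats)
preds <- predict_ebl(fit, feats[feats$split == "test", ])
stratified_report(preds)

pp <- per_patient_report(preds)
ggplot2::autoplot(pp$bland_altman)
```

## Known limitations

* The backbone families are named after the architectures they gesture at;
  none is a faithful reconstruction, and results with them say nothing about
  the originals.
* The blood-evidence weight is a probability, not grams; the
  `ground_truth_mass` mode exists precisely to quantify, on synthetic data,
  how much that proxy costs.
* The mass→appearance mapping of the simulator is a modelling choice, not a
  calibration against real gauze photographs; absolute error figures on
  synthetic data do not transfer to clinical imagery.
* Training is single-threaded CPU R; the engine is adequate for the shipped
  study sizes and deliberately not a general-purpose learning library.
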