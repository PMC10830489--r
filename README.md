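# gauzeloss

Automated estimation of intraoperative blood loss (EBL) from laparoscopic
images of surgical gauze.

Manual EBL assessment — weighing each blood-soaked gauze on a scale — is
accurate but slow and labour-intensive. `gauzeloss` implements an image-based
pipeline for the task: detect the gauze in a laparoscopic frame by tile
classification, quantify how *crumpled* the fabric looks with a texture
statistic, and regress the absorbed blood mass in grams from the masked gauze
image fused with the texture features. The package also ships a synthetic
laparoscopic scene generator with exact ground truth (masks, per-pixel blood
mass maps), so every stage is trainable and testable without clinical data.

## The method

**Detection.** Frames are cut into 64-px tiles, each classified into four
states — background tissue, clean gauze, stained gauze, soaked gauze — by a
small CNN. A pixel joins the gauze mask when the mean gauze probability of
the tiles covering it is ≥ 0.5 (plus a 5-px morphological closing).

**Crumpled state value (CSV).** For each pixel the local binary pattern code
with `p = 8` neighbours on a circle of radius `r = 3`:

    LBP(c) = Σ_{k=0..7} s(g_k − g_c) · 2^k ,   s(x) = 1 if x ≥ 0, else 0

and the CSV is the mean code over the detected gauze region — a scalar
summary of local texture variation, which rises as folds and wrinkles break
the flat weave.

**Regression.** Three fused variants are implemented and compared:

| variant | inputs |
|---|---|
| base    | masked gauze image only |
| CS      | image + whole-region CSV through an MLP |
| P-W CS  | image + vector of per-patch CSVs, each weighted by the patch's blood evidence (stained + soaked probability) |

Training uses MAE loss, batch size 32 and learning rate 5e-3; predictions
are clamped at 0 g. Evaluation covers MAE/MAPE/MSE stratified by true EBL
(≤3 g, 3–5 g, >5 g), per-patient totals, grouped stratified k-fold CV and
Bland–Altman agreement.

## Worked example

```r
library(gauzeloss)

# synthetic tile set and detector
tiles    <- generate_tile_dataset(200, seed = 1)
detector <- train_tile_classifier(tiles, train_config = list(epochs = 20))
glance(detector)
#> # A tibble: 1 x 7
#>   backbone  n_params epochs best_val_loss test_accuracy test_sensitivity_pct test_specificity_pct
#>   <chr>        <dbl>  <int>         <dbl>         <dbl>                <dbl>                <dbl>
#> 1 small_cnn     7220     20        0.0909         0.985                  100                  100

# scenes, features, and a P-W CS regressor
ss    <- generate_scene_set(300, seed = 11)
feats <- regression_features(ss$scenes)
feats$split <- stratified_split(feats$ebl_g, c(3, 1, 1), 11)
fit   <- train_regressor(regression_config(variant = "pwcs", epochs = 35), feats)

preds <- predict_ebl(fit, feats[feats$split == "test", ])
stratified_report(preds)
#> # A tibble: 4 x 6
#>   stratum    level         n mae_g mape_pct mse_g2
#>   <chr>      <chr>     <int> <dbl>    <dbl>  <dbl>
#> 1 le3g       per_gauze    23 0.455     30.6  0.416
#> 2 g3to5      per_gauze    21 0.845     21.9  1.39
#> 3 gt5g       per_gauze    16 1.78      24.4  4.45
#> 4 all_pooled per_gauze    60 0.945     25.9  1.83
per_patient_report(preds)$bland_altman
#> <bland_altman> bias -0.424 g, limits of agreement [-3.922, 3.074] g
```

The detector summary reads: on a held-out synthetic split the tile
classifier finds every gauze tile (sensitivity 100%) and accepts no
background tile as gauze (specificity 100%). The stratified report gives
MAE (grams), MAPE (%) and MSE per true-EBL bin and pooled; the
Bland–Altman line summarises per-patient agreement, with limits in grams.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/gauzeloss.R simulate --n 100 --out data/ --seed 1
Rscript inst/cli/gauzeloss.R pipeline --out run1/ --seed 1
```

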