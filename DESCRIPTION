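Package: gauzeloss
Title: Automated Estimation of Intraoperative Blood Loss from Surgical
    Gauze Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating intraoperative blood loss (EBL, in grams)
    from laparoscopic images of surgical gauze. Implements a tile-based gauze
    detector over the four tile states (background tissue, clean, stained and
    soaked gauze), local-binary-pattern texture analysis yielding a crumpled
    state value (CSV) per gauze region, and multi-input regression networks
    that fuse a masked gauze image with either a single CSV or a vector of
    blood-evidence-weighted patch CSVs. Ships a synthetic laparoscopic scene
    generator with known gauze masks and per-pixel blood-mass maps so the
    whole pipeline is trainable and testable without clinical data, plus the
    full evaluation protocol: MAE/MAPE/MSE, EBL-stratified reports,
    per-patient aggregation, grouped stratified k-fold cross-validation and
    Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
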