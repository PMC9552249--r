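Package: eoescan
Title: Whole-Slide Eosinophil Quantification for Eosinophilic Esophagitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-slide image analysis pipeline for eosinophilic
    esophagitis (EoE) histopathology. Provides tile planning and OR-fusion of
    patch masks, rasterization of expert point annotations into multi-label
    training masks, a pluggable multi-label segmenter contract with a compact
    nested encoder-decoder reference implementation and a ground-truth oracle,
    per-image segmentation metrics with competition-rank model selection,
    area-based intact-eosinophil counting, a sliding high-power-field peak
    eosinophil count (PEC) with bounded-memory window processing, disease
    activity classification at the 15 eosinophils per 0.3 mm2 cutoff, ROC and
    count-calibration evaluation, and a synthetic H&E-like slide generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    EBImage
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
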