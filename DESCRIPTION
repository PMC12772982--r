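Package: cervhsi
Title: Hyperspectral Tissue-Index Analysis of Cervical Lesions
Version: 0.1.0
Authors@R:
    person("cervhsi", "maintainers", email = "cervhsi@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for detecting cervical intraepithelial
    neoplasia (CIN) related tissue changes in hyperspectral reflectance
    images. Builds consensus reference masks from multiple examiners'
    annotations (per-pixel agreement maps, pairwise intersection-over-union),
    estimates the colposcope-to-hyperspectral homography from landmark
    correspondences and transfers annotations between frames, extracts
    band-ratio chromophore indices (tissue water, hemoglobin, oxygen
    saturation, near-infrared perfusion) from masked cube regions, and
    compares lesion versus healthy tissue with paired Wilcoxon signed-rank
    tests, Hodges-Lehmann shift estimates, and bootstrap confidence
    intervals. Includes a seeded Beer-Lambert phantom generator so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
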