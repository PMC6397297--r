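Package: fibreDRC
Title: Single-Cell Stress-Fibre Morphometrics and Expression
    Dose-Response Regime Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies single cells in multi-channel fluorescence
    micrographs (GFP-tagged probe, cytoskeletal stain, DAPI): segments
    cells, nuclei and actin stress fibres, measures per-cell
    morphometric descriptors and a total-GFP expression surrogate,
    builds dose-response curves of pooled descriptor statistics against
    expression, and segments the curves into no-effect, dose-response
    and saturation regimes with a windowed ratio-of-variances
    statistic. Includes time-lapse metrics (migration distance and
    directionality, F-actin interframe change, drug-induced
    disassembly), nuclear-to-cytosolic intensity ratios and
    fibre-colocalized intensity, and a seeded synthetic-image generator
    with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
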