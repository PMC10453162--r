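Package: cicquant
Title: Quantification of Cell-in-Cell Structures in Co-Incubation and Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies cell-in-cell (CIC) structures formed by
    non-professional phagocytosis: dead cells engulfed by viable tumour cells.
    Provides synthetic two-colour co-incubation scenes and immunostained
    tissue-microarray cores with planted ground truth, channel segmentation,
    host/engulfed pair scoring (containment, circularity, nuclear crescent
    imprint), CIC rates and per-area densities, semiquantitative E-cadherin
    scoring, and the associated group statistics and reporting rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
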