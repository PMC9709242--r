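Package: spermaquant
Title: Quantitative Image Analysis of C. elegans Sperm Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation, morphometry and intensity quantification for
    Caenorhabditis elegans sperm microscopy assays: spermatid shape metrics
    and rule-based sperm-activation classification, JC-1 mitochondrial
    membrane-potential ratios and per-mitochondrion morphology, redox-probe
    and whole-animal reporter intensities, and uterine-zone sperm
    localization with track-velocity statistics. Includes a ground-truthed
    synthetic microscopy generator so every pipeline stage can be validated
    without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
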