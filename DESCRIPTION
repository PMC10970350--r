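Package: lbclpanel
Title: Targeted-Panel Sequencing Analysis of Large B-Cell Lymphomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end downstream analysis pipeline for targeted
    amplicon-panel sequencing of large B-cell lymphomas from
    formalin-fixed tissue: FFPE-aware sample quality control
    (transition/transversion exclusion), rule-based variant filtering and
    pathogenicity classification, amplicon-coverage copy-number calling,
    molecular phenotyping (Hans cell-of-origin, double-expressor status,
    disease categorization, LymphGen membership handling), cohort
    summarization with oncoprint export, and competing-risks survival
    analysis. Includes a synthetic-data generator with known truth labels
    so every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    cmprsk,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
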