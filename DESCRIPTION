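Package: evpanel
Title: Spectral-Count Differential Abundance and Plasma EV Biomarker Panel
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free spectral-count (PSM) quantification with G-test
    differential abundance for wild-type versus 5xFAD mouse multi-proteomes,
    cross-proteome comparison of significantly altered protein sets,
    directional pathway activation scoring on user-supplied gene sets,
    staging and class-1/2/3 pattern assignment for human plasma
    extracellular-vesicle biomarker panels, and sequential feature-accumulation
    SVM panel selection with repeated stratified cross-validation and ROC/AUC
    evaluation. Includes a synthetic-data generator with planted ground truth
    so every stage is testable without raw mass-spectrometry data, and an
    end-to-end pipeline driver with a deterministic run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
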