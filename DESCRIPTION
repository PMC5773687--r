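Package: sdmrange
Title: Ensemble Species Distribution Models for Climate-Driven Range
    Shifts and Protected-Area Invasion Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An ensemble species-distribution-modelling pipeline for
    projecting range shifts of invasive plants under climate scenarios and
    flagging protected areas newly exposed to invasion. Provides occurrence
    spatial filtering, Pearson collinearity pruning, surface-range-envelope
    (BIOCLIM-style) models, envelope-exclusion pseudo-absence sampling,
    repeated stratified 70/30 evaluation with AUC and the true skill
    statistic (TSS), TSS-weighted ensembles with max-TSS binarization,
    full-dispersal gain/loss/stable range accounting, and a
    protected-area overlay risk report. A virtual-species simulator with
    exported ground truth supplies every input needed to validate the
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mgcv
Config/testthat/edition: 3
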