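Package: nestseg
Title: Tumor-Nest/Stroma Tissue Segmentation and Region-Stratified Immune
    Cytometry for Multiplex IHC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments intratumoral tissue in multiplex immunohistochemistry
    (mIHC) images into tumor cell nests and intratumoral stroma using Huang
    fuzzy thresholding and mathematical morphology, gates single cells into
    leukocyte lineages by marker-positivity hierarchies, computes
    region-stratified cell densities and nest/stroma polarization metrics,
    and runs the associated prognostic statistics (Kaplan-Meier, log-rank,
    Cox proportional hazards, Spearman correlation, mean/median/fixed/ROC
    cutoff stratification). Includes a synthetic slide and cohort generator
    with known ground truth so every stage is testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    survival,
    pROC,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
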