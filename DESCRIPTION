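Package: graftPLS
Title: Empirical Modelling of Bone-Graft Physico-Chemical Characteristics
    and Intra-Oral Bone Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the physico-chemical characteristics of commercial
    intra-oral bone graft substitutes (chemical composition, macroporosity,
    image-derived surface roughness) to six-month in vivo bone-to-material
    contact through a from-scratch univariate partial-least-squares
    regression (NIPALS) engine with leave-one-out cross-validation,
    RMSE-based component selection, variable-importance-based backward
    elimination and original-scale equation export. Ships the seven-graft
    study table as a builtin dataset, profile-roughness (Pa, Pq, Pt) and
    macroporosity area-fraction quantification from binarized micrographs,
    and synthetic generators (predictor tables with known coefficients,
    granule silhouettes with known boundary roughness, colonization mask
    pairs) so every stage is verifiable without the original explants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
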