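Package: oromsi
Title: Multispectral Diffuse-Reflectance Imaging Toolkit for Oral Lesion Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for four-band intraoral multispectral imaging: a
    two-chromophore tissue phantom simulator, exposure auto-calibration,
    pixel-wise diffuse-reflectance ratio maps with pseudo-color rendering,
    modified Beer-Lambert inversion of oxy- and deoxyhemoglobin
    concentrations, region-of-interest hotspot scoring of lesions,
    mean-of-means threshold classifiers with a versioned local model
    registry, and diagnostic-accuracy reporting (sensitivity, specificity,
    predictive values, ROC-AUC, class summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
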