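Package: scmseg
Title: Spiking Cortical Model Segmentation of Nuclei in Reflectance
    Confocal Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated segmentation of cell nuclei in reflectance confocal
    microscopy images of epithelial tissue using a pulse-coupled neural
    network, specifically a fire-once spiking cortical model. Provides the
    full pipeline (background removal, iterative pulse-driven gamma
    filtering, segmentation-mask growth from the pulse-time matrix, and a
    neural-network object classifier that removes likely false positives),
    a synthetic image model of epithelial nuclei with ground-truth labels,
    and a quantitative evaluation harness: object- and pixel-based
    sensitivity, pixel specificity, F-measure, nuclear-to-cytoplasmic
    ratio and nuclear morphometrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    nnet,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
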