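Package: gnnsurv
Title: Graph Neural Network Survival Models for Whole-Slide Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic modelling of whole-slide histopathology
    images with spatial patch graphs. Implements saturation/Otsu tissue
    masking, tiling of masked tissue into fixed-size patches, pluggable
    patch encoders, k-nearest-neighbour graph construction, graph neural
    network backbones (graph convolution and graph attention) with four
    graph pooling strategies trained jointly with a Cox proportional
    hazards head by negative partial log-likelihood, Breslow baseline
    survival estimation, horizon survival probabilities and threshold risk
    stratification with patient-level cross-validation, explainer-style
    node-importance heatmaps, the accompanying survival and contingency
    statistics, and synthetic slide and cohort generators so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    glmnet,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
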