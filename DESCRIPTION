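Package: defcyto
Title: Deformability Cytometry Feature Extraction and Multiparameter Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational workbench for extensional-flow deformability
    cytometry. Extracts fifteen biophysical parameters (size, deformability,
    deformation timing, strain and boundary-morphology metrics) from per-cell
    high-speed image stacks via segmentation, sub-pixel contours and radial
    boundary traces, and provides the accompanying multiparameter statistical
    stack: Gaussian-mixture clustering with a within/between clustering-error
    statistic and hierarchical feature elimination, support-vector-machine
    classification with cross-validation, ROC analysis and recursive feature
    elimination, flow-cytometry-style gating (threshold and fitted quantile
    ellipse), spike-in mixture deconvolution with limit-of-detection
    estimation, similarity matrices, PCA/LDA projections, and bead-based
    stiffness calibration. A synthetic event simulator renders ground-truthed
    viscoelastic cell events so that every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    e1071,
    MASS,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    mclust
Config/testthat/edition: 3
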