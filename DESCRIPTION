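Package: tsrquant
Title: Automated Tumor-Stroma Ratio Quantification from Whole-Slide Images
Version: 0.1.0
Authors@R: person("TSR", "Maintainers", email = "maintainers@tsrquant.org", role = c("aut", "cre"))
Description: A multi-step pipeline for automatic tumor-stroma ratio (TSR)
    quantification in pancreatic-cancer whole-slide images: epithelium label
    generation from CK8/18-DAB immunohistochemistry via color deconvolution,
    two-stage epithelium and tumor-epithelium segmentation with five-fold
    cross-validation and sliding-window inference, alpha-hull tumor-bulk
    delineation, whole-bulk TSR computation, and TSR-based survival analysis
    (horizon-classification AUC and Kaplan-Meier stratification). Ships a
    synthetic slide and cohort generator with exact ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    survival,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
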