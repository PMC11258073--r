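Package: rootnoise
Title: Automatic Aortic Root Noise and Signal-to-Noise Measurement for
    Coronary CT Angiography Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures image noise and vascular attenuation in coronary CT
    angiography (CCTA) without manual interaction. A compact 3D U-Net,
    implemented and trained in-package, segments the aortic root and the
    proximal left main (LM) and right coronary arteries on a resampled
    working grid. The LM-aorta contact point defines a seven-slice
    measurement zone inside the radially shrunk aortic root in which mean
    attenuation (HU), noise (standard deviation of HU) and signal-to-noise
    ratio are computed. A synthetic CT-phantom generator with exact ground
    truth supports training, calibration and end-to-end testing, and a
    statistical layer provides method-agreement analysis (Spearman,
    Bland-Altman, absolute errors), group comparisons and ROC/AUC with
    Youden cutoffs for flagging non-diagnostic examinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    pROC,
    nortest,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
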