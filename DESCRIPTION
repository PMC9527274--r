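Package: pvcorigin
Title: ECG Criteria for Localizing Outflow-Tract Premature Ventricular
    Contractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating the origin of idiopathic premature
    ventricular contractions (PVCs) with a left-bundle-branch-block pattern
    between the septal right ventricular outflow tract (s-RVOT) and the
    aortic sinus cusp of the left ventricular outflow tract (LVOT-ASC) from
    12-lead ECG wave amplitudes.  Implements the precordial R-S difference
    index (V2R + V3R + V4R - V1S) and four comparator criteria (V2S/V3R
    index, RV1-V3 transition ratio, V2 transition ratio, and
    (V1S+V2S)-(V1R+V2R)), ROC/AUC evaluation with Youden-optimal cutoffs,
    group-comparison statistics, a logistic joint model, and a calibrated
    zero-inflated log-normal synthetic-cohort generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
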