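Package: stressknee
Title: Automated Anterior Tibial Translation Measurement in Knee Stress
    Radiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for computer-assisted analysis of lateral knee stress
    radiograph pairs. Segments the femur, tibia and femoral condyles
    (minimal-cost edge paths, shaft axis fitting, a point-distribution
    condyle shape model), measures anterior tibial translation by four
    geometric methods together with four technical factors (flexion angle,
    intercondylar distance, force-joint distance and angle), and evaluates
    diagnostic performance for anterior cruciate ligament tear (empirical
    ROC curves, Youden-optimal cutoffs, two-by-two diagnostic metrics with
    confidence intervals, univariate logistic factor analysis). Because
    clinical stress radiographs are rarely shareable, a phantom generator
    renders radiograph-like image pairs with exact geometric ground truth,
    and a cohort simulator draws per-patient measurement tables, so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
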