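Package: wardflow
Title: Dynamic Prediction of Clinical Deterioration from Event-Stream
    Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dynamic prediction of clinical
    deterioration (the composite of unplanned intensive-care transfer and
    in-hospital death) in hospitalized patients. Provides a synthetic
    event-stream EHR generator with a planted latent severity signal,
    admission stitching and cohort construction, multi-domain tokenization
    (diagnosis roll-up, quantile-binned laboratory tokens, note-token
    cleaning), leakage-free risk-assessment sampling on an assessment-rate
    by prediction-window grid, an entity-embedding recurrent ensemble with
    attention pooling trained by hand-written backpropagation, post-hoc
    isotonic recalibration, bootstrap evaluation of discrimination and
    calibration, and gradient-based Shapley token attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
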