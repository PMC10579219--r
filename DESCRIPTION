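Package: swallowphase
Title: Temporal Localization of Swallowing Phases in Fluoroscopic Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frame-level temporal localization of the seven swallowing phases
    measured in videofluoroscopic swallowing studies (VFSS). Implements the
    event calculus that turns the seven labeled swallowing events (oral phase
    start, bolus past mandible, hyoid burst, laryngeal vestibule closure onset
    and offset, upper esophageal sphincter opening and closure) into the seven
    clinical temporal parameters in milliseconds; a seeded synthetic
    fluoroscopy-like video generator calibrated to published phase-duration
    statistics; windowed frame-labeling schemes; three ResNet3D-18
    architectural variants (center-window DEFAULT, BIDIRECTIONAL forward and
    backward streams, and CONV-SA with multi-head self-attention over frame
    features) with a self-contained 3D-convolution training engine; the
    frame-level evaluation metrics (accuracy, precision, recall, F1, average
    precision); and an end-to-end reproducible experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
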