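Package: FrontalGait
Title: Front-View Video Gait Analysis and UPDRS-Gait Severity Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring Parkinson's disease gait severity from a
    single front-facing camera. A walking subject's silhouette height is
    tracked across video frames to form a one-dimensional height signal,
    which is face-height adjusted, min-max normalized, smoothed, quantized
    into fixed-size partitions and split into forward and backward walks at
    the closest-approach maximum. Five gait features are computed from the
    signal (average stride time, detrended-fluctuation exponent, amplitude
    entropy, spectral-centroid variability and valley-to-peak time) and a
    one-vs-all support vector machine with the Pearson VII universal (PUK)
    kernel classifies UPDRS-gait levels 0, 1 and 2 under stratified 10-fold
    cross-validation. A synthetic gait-signal simulator and silhouette
    renderer provide labeled ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    kernlab,
    pROC,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Visualization
RoxygenNote: 7.3.3
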