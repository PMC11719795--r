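Package: pivotshift
Title: Quantifying Knee Rotational Laxity from Smartphone Gyroscope
    Recordings of the Pivot-Shift Maneuver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing three-axis smartphone gyroscope recordings
    of the clinical pivot-shift test used to assess anterior cruciate
    ligament (ACL) injury. The X-axis angular-velocity trace is quality
    controlled, split into three contiguous segments, and summarised by
    segment-wise time-domain and Fourier-domain features. Feed-forward
    neural networks classify each test into one of eight maneuver-execution
    classes and, for standard executions, grade the injury on the 0-3 IKDC
    scale. Includes the diagnostic-accuracy statistics used to evaluate
    such classifiers (per-class confusion counts and derived metrics,
    Pearson chi-square association of class distributions, Mann-Whitney U,
    ROC/AUC), a synthetic-signal simulator with known class and grade
    labels, and a command-line interface binding the pipeline stages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
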