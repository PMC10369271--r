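Package: pdglove
Title: Multimodal Sensor-Glove Assessment of Hand Function in Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Signal-processing and grading pipeline for a multimodal sensor
    glove that quantifies hand function in Parkinson's disease. Provides
    exponentially weighted average, median, zero-phase Butterworth bandpass
    and adaptive scalar Kalman filtering of bend, pressure and accelerometer
    recordings; min-max normalised finger-flexibility grading (F0-F4);
    one-dimensional K-means interval partitioning of muscle-strength maxima
    onto the Lovett scale (M0-M5); triaxial acceleration fusion into a
    nine-element time/frequency tremor feature vector; a from-scratch 9-6-3
    back-propagation neural network with stratified cross-validation and
    multiclass evaluation; Cohen's kappa with its large-sample null-variance
    Z score and single-measurement absolute-agreement intraclass correlation
    for clinical agreement; and synthetic generators for tremor, gesture and
    grip recordings so the whole pipeline runs without hardware.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
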