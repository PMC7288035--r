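Package: eegsm
Title: EEG Channel-Correlation Analysis and a Topographic-Map Soft Sensor
    for Shopfloor-Management Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize shopfloor-management behavior classes from
    16-channel electroencephalography (EEG). Provides a synthetic generator of
    correlated multichannel EEG whose cross-channel Pearson correlation
    structure encodes sensor-group hypotheses (prefrontal, occipital,
    temporal, parietal), a zero-phase Butterworth preprocessing chain
    (drift-removing high-pass, 50 Hz low-pass, amplitude normalization to
    plus/minus 10), rendering of 0.5 s segments as jet-colormap scalp
    topographic maps, per-recording correlation matrices with Fisher-z
    category averaging and hypothesis evaluation, and a four-class
    convolutional soft sensor trained with subject-pair-disjoint splits and
    evaluated by confusion-matrix accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    png,
    jsonlite,
    data.table,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
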