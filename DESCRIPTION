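Package: propsignal
Title: Automated Delineation and Classification of PROP-Evoked Tongue
    Biopotentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automatic processing of tongue surface biopotential
    recordings evoked by a 6-n-propylthiouracil (PROP) stimulus, for
    objective taster-status screening. Provides low-pass filtering and
    rate conversion of the raw recording, derivative-based detection of
    the depolarization onset (knee point), delineation of the waveform by
    sum-of-exponentials and rational curve models with analytic feature
    extraction (areas, amplitudes, slopes, half-area time), and a
    repeated stratified cross-validation harness (KNN and SVM) for the
    non-taster / medium-taster / supertaster and TAS2R38 diplotype
    classification problems. A seeded synthetic-recording generator
    supplies annotated cohorts with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    e1071,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
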