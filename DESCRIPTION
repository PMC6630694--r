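Package: pcgscreen
Title: Phonocardiogram Screening with Cost-Sensitive Heart-Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for phonocardiogram (PCG) abnormality
    screening: WAV ingestion of heart-sound recordings, a seeded synthetic
    PCG generator with a sensor-chain (pre-amplifier, analog band-limit,
    ADC quantization) simulator, band-pass filtering and spike removal,
    S1-anchored heart-cycle segmentation via a Shannon-energy envelope,
    a 27-value per-cycle feature extractor (time-domain statistics,
    spectral features, 13 MFCCs), regularized neighborhood component
    analysis feature weighting, cost-sensitive k-nearest-neighbor and
    random-subspace ensemble classifiers with stratified cross-validation,
    and a full confusion-matrix metric suite for imbalanced screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
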