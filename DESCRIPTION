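Package: zebrarep
Title: Vocal Repertoire and Individuality Analysis for Plains Zebra Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying the vocal repertoire and
    individual vocal signatures of plains zebras (Equus quagga) and similar
    species. Provides extraction of twelve standard acoustic features
    (fundamental-frequency statistics, spectral energy quartiles, peak
    frequency, duration and amplitude-modulation metrics) from annotated WAV
    recordings; mel-spectrogram preparation with zero-padding, onset
    alignment and a time-shift-aware spectrogram distance; supervised call
    type classification from features (gradient boosting with
    Shapley-value feature screening) and from spectrograms (a small
    convolutional network); unsupervised call clustering (2-D embedding,
    k-means, elbow selection, within/between distance diagnostics); and a
    vocal-individuality chain of Kaiser-Meyer-Olkin screening, principal
    component reduction, discriminant function analysis and a nested
    permuted DFA with a restriction factor. A synthetic-call generator with
    known ground truth (call type, per-individual random effects, sex and
    location structure) makes every stage testable without field recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
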