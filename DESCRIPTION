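Package: ecgsrqa
Title: Atrial Fibrillation Screening from Low-Cost ECG Charts via Symbolic Recurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assisting atrial-fibrillation screening with low-cost
    single-lead ECG recorders. Digitizes scanned or exported ECG chart images
    (gridded paper-style traces) into uniformly sampled waveforms, smooths them
    and detects R peaks to obtain RR-interval series, optionally calibrates RR
    intervals against a gold-standard device by linear regression, computes
    symbolic recurrence quantification (ordinal-pattern) and RR-distribution
    covariates, and classifies windows as normal sinus rhythm or atrial
    fibrillation with a logistic model whose probability threshold is chosen
    on the ROC curve. Includes synthetic generators for RR series, PQRST-like
    waveforms and rendered chart images so the full pipeline can be exercised
    and validated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    png,
    igraph,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    EBImage,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
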