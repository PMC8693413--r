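Package: tcdqeeg
Title: Multimodal Transcranial Doppler and Quantitative EEG Prognostics for Large Hemispheric Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bedside multimodal prognosis modelling for large hemispheric
    infarction. Computes quantitative EEG spectral indices (Welch power
    spectra, relative band powers, delta/alpha and (delta+theta)/(alpha+beta)
    ratios, brain symmetry index), extracts transcranial Doppler velocity
    measures with TIBI flow grading and rule-based offending-vessel
    classification, and fits 90-day survival models (Cox proportional
    hazards with backward elimination, Kaplan-Meier curves, log-rank tests)
    and prognostic ROC comparisons (DeLong). Includes synthetic-data
    generators for EEG recordings, Doppler envelopes and survival cohorts
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pROC,
    signal,
    stats,
    survival,
    utils,
    rlang,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
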