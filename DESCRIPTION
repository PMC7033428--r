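Package: eegrt
Title: Predicting Reaction-Time Delays from Pre-Cue EEG Bandpower
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for predicting single-trial reaction-time delays from
    the EEG segment immediately preceding a visual cue. Pre-cue windows are
    decomposed into ten classical frequency bands by zero-padded FFT
    filtering, summarized as log-variance bandpower features, and fed to
    tuned regression models (LASSO, kernel ridge, RBF support vector
    regression) evaluated with repeated random train/test splits, a
    shuffled-label control, and robust statistics. Includes a synthetic
    session generator with planted, recoverable EEG-delay couplings for
    validating every stage, plus readers and writers for EDF and long-form
    CSV recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
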