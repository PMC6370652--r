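Package: cardiocause
Title: Temporal Causality Analysis of Cardiorespiratory Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates directed temporal-causal links between cardiac and
    respiratory activity recorded as single-lead ECG plus thoracic
    impedance. Derives tidal-volume, instantaneous respiratory-rate and
    instantaneous heart-rate representations (25 Hz and 2.5 Hz signal
    sets, beat-by-beat sequences), screens stationarity with an augmented
    Dickey-Fuller test, and quantifies coupling with pairwise-conditional
    time-domain Granger causality (BIC order selection, F tests,
    prediction-improvement parameterization), Geweke spectral Granger
    causality with peak extraction, an extended zero-lag Granger variant
    for beat sequences, and additive-noise (TiMINo-style) causal
    discovery with residual-independence testing. Includes cohort
    summaries, rank-based group tests, random-forest recursive feature
    elimination, and a synthetic generator of RSA-coupled recordings for
    validation without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    randomForest,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
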