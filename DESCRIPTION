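Package: pttbp
Title: Cuffless Blood Pressure Estimation from Smartphone Pulse Transit Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pulse-transit-time (PTT) based cuffless blood pressure
    estimation from two-channel smartphone recordings (seismocardiogram from
    the inertial measurement unit, photoplethysmogram from the camera).
    Provides a synthetic signal generator with known ground-truth PTT and
    blood pressure; the signal chain used by PTT devices (zero-phase IIR
    band-pass filtering, PPG onset detection, onset-anchored SCG
    segmentation, ensemble averaging, aortic-opening detection); systolic and
    diastolic pressure estimation via the Bramwell-Hill and Moens-Korteweg
    equations with a three-session individual calibration; and the validation
    statistics used to grade cuffless devices (paired difference summaries,
    absolute-difference bands, Bland-Altman limits of agreement,
    per-participant coefficient of variation, AAMI/ESH/ISO criterion 1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
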