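Package: hrvmech
Title: Mechanistic Heart Rate Variability Analysis from Sinoatrial Node Automaticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic framework for interpreting heart rate variability
    (HRV). A closed-form model of sinoatrial node automaticity predicts heart
    period, heart rate and their low-frequency (LF) and high-frequency (HF)
    variability amplitudes from four action-potential parameters under
    sympathetic and parasympathetic modulation. The package couples the model
    to a synthetic beat-series generator, a complete time-domain (SDNN, RMSSD)
    and frequency-domain (spline resampling, averaged overlapping-segment
    spectra, LF/HF band powers from both heart-period and heart-rate
    representations) HRV pipeline, and a rule engine that maps directional
    changes in the metrics to inferences about cardiac autonomic tone,
    including the cross-representation LF/HF ratio computed from heart-rate LF
    power over heart-period HF power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
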