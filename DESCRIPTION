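Package: alarmid
Title: Identification of Audible Medical Alarms from Audio Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Acoustic identification of audible medical alarms (IEC
    60601-1-8 style repeating tone bursts) in mono WAV audio. Extracts an
    alarm's spectral signature (up to five dominant frequencies from the
    whole-clip power spectral density), its repeat interval (first peak of
    the autocorrelation of a log-compressed band-power trace), and the
    width of that autocorrelation peak, and matches the features against a
    template database. Ships a reference 14-alarm template table, a
    synthetic test bench (parametric alarm synthesis, seeded pink noise,
    RMS signal-to-noise-ratio mixing, discrimination grids), and the
    evaluation protocols (SNR sweeps, negative-predictive-value runs,
    threshold-performance grids, threshold tuning).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'audio-io.R'
    'spectral.R'
    'templates.R'
    'identify.R'
    'synthbench.R'
    'evaluation.R'
    'alarmid-package.R'
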