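Package: ovosex
Title: Non-Invasive In Ovo Chicken Egg Sexing from Bioimpedance Ratio Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for determining the sex of incubating chicken
    eggs from four-electrode bioimpedance sweeps. Implements self-normalized
    electrode-pair ratio spectra, per-day Welch two-sample t-test scans across
    the frequency grid with a persistence rule that locates the discriminative
    frequency band and its onset day, a ratio-threshold sex classifier
    evaluated against PCR ground truth, electrode repeatability QC, and a
    Cole-model synthetic sweep generator calibrated to the reference cohort so
    every stage is testable without raw instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
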