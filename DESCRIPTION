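Package: pulcon
Title: Quantitative 1H NMR of Mineral Oil Hydrocarbons by PULCON External Calibration
Version: 0.1.0
Authors@R: person("LAVES", "NMR Tools", email = "nmr@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of mineral oil saturated hydrocarbons
    (MOSH), mineral oil aromatic hydrocarbons (MOAH), other compounds and the
    EFSA PAH4 marker group in pure mineral-hydrocarbon products from 1D 1H NMR
    spectra, using the PULCON principle with an ERETIC calibration factor
    established from an external quantification reference sample. Includes a
    JCAMP-DX reader/writer (AFFN and DIFF/DUP), FID processing (apodization,
    zero filling, Fourier transform, automatic phase and baseline correction,
    TMS referencing), region integration with solvent exclusion windows,
    limit-of-detection estimation, series-level quality control (control-sample
    recovery gate, coefficient of variation, spike recovery), a seedable
    synthetic-spectrum simulator with a ground-truth ledger, and a command-line
    interface for series processing and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
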