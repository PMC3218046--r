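Package: fretlin
Title: Linear Quantification of Unimolecular FRET Probe Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward models and estimators for quantitative measurements of
    unimolecular FRET (Foerster resonance energy transfer) biosensors.
    Implements steady-state solutions of the probe activation cycle driven by
    opposing Michaelis-Menten enzymes, emission-spectrum band models and
    crosstalk coverage coefficients, ratiometric forward models contrasting
    the standard acceptor/donor ratio R (non-linear in the FRET-competent
    fraction) with the linear alternative ratio R_alt (donor emission over
    directly excited acceptor emission), fluorescence-lifetime (FLIM) mixture
    models with a frequency-domain phase-lifetime simulator, and the
    two-point calibration that converts any linear FRET observable into the
    fraction of active probes.  A synthetic-data module reproduces the
    statistical structure of plate-reader mixture titrations so every
    estimator is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
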