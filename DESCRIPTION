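Package: oxydeficit
Title: Breath-by-Breath Oxygen-Deficit Computation and Diagnostic Accuracy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for noninvasive gas-exchange scoring from expired-gas
    waveforms. Segments 100 Hz capnography/oximetry traces into breaths,
    extracts end-tidal O2 and CO2 plateaus, detects the 45-second end-tidal
    CO2 steady state, and averages five consecutive steady-state breaths
    into alveolar gas tensions (PAO2, PACO2). Converts pulse-oximetry
    saturation into a calculated arterial oxygen tension (gPaO2) by
    inverting the Hill saturation curve (n = 2.88) with a CO2-corrected
    P50, and reports the oxygen deficit OD = PAO2 - gPaO2, a surrogate for
    the alveolar-arterial oxygen gradient. Includes synthetic trace and
    patient-cohort generators with planted ground truth, logistic
    regression with Wald inference and Box-Tidwell linearity checks, ROC
    analysis with DeLong confidence intervals and Youden operating points,
    and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
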