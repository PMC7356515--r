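Package: pkpdsynergy
Title: Minimal PKPD Simulator for Combined Antiangiogenic, Immuno- and
    Radiotherapy in NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tumor growth under combined antiangiogenic therapy,
    immunotherapy and radiotherapy with a minimal eight-state
    pharmacokinetic-pharmacodynamic (PKPD) compartment model for non small
    cell lung cancer (NSCLC). Drug and radiation action is described by Hill
    dose-effect response surfaces over potency-normalized agent levels, with
    a synergy coefficient and a patient-response exponent; radiotherapy is
    supported by a linear-quadratic cell-survival module with an
    incomplete-repair correction. Includes dosing-schedule builders for
    weekly drug administration and three fractionated radiotherapy
    protocols, a deterministic fixed-step Runge-Kutta integrator, and
    experiment runners for control, protocol-comparison, synergy-sweep and
    resistance-sweep studies, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
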