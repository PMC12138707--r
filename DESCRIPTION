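Package: synkin
Title: Anion-Binding and Aggregation Kinetics of Short Peptides by NMR
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis chain for peptide anion-binding and
    aggregation studies monitored by solution NMR. Implements the closed-form
    Finke-Watzky two-step nucleation/autocatalytic-growth model with analytic
    phase-time extraction from the zeros of the jerk (third time derivative),
    nonlinear fitting of monomer-loss traces, per-residue 1:1 fast-exchange
    binding isotherm fits for weak anion association constants, chemical shift
    perturbation (bubble-map) analysis, Karplus-equation coupling/dihedral
    analysis, and variable-temperature amide shift coefficients. A synthetic
    data module generates every input the pipeline consumes so all stages are
    testable without experimental spectra.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
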