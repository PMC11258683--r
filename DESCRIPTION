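Package: kproof
Title: Kinetic Proofreading in DNA Strand-Displacement Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action models of DNA strand-displacement kinetic-proofreading
    networks: builders for the template-binding, template-recovery, full-discard,
    templated-dimerization and SNP-detection motifs; deterministic (ODE) and
    exact stochastic (Gillespie) simulation; a fluorescence observation and
    calibration layer emulating two-channel plate-reader traces; a synthetic-data
    generator at the study designs; staged weighted-least-squares rate-constant
    estimation with reporter-set enumeration and selection; and specificity
    statistics (discrimination factors, catalytic turnover, initial rates, and
    the idealized Hopfield proofreading cycle).
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
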