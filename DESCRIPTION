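Package: covkin
Title: Progress-Curve Kinetics for Irreversible Serine Protease Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes irreversible (covalent) inhibitors of the
    neutrophil serine proteases from continuous fluorogenic assays.
    Fits single-exponential progress curves for the apparent first-order
    inactivation constant k_obs, converts seven-point inhibitor ladders
    into the second-order rate constant kinact/KI with the (1 + [S]/KM)
    substrate-competition correction, implements the 25 uM / 15 min
    screening triage, and builds cross-protease (elastase, proteinase 3,
    cathepsin G) selectivity profiles with fold changes against a
    reference compound. A mechanistic mass-action simulator of the
    two-step covalent inhibition scheme generates plate-reader-like
    datasets so the whole pipeline is testable without raw assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
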