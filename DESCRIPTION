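Package: morphostate
Title: Morphological State-Transition Dynamics from Aggregate Population
    Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers phenotypic state-transition dynamics from aggregate
    three-state population snapshots, as arise in quantitative imaging of
    growth-factor-induced epithelial-to-mesenchymal transition. Provides a
    discrete-time multi-state population model with birth and death (in
    expectation and as a stochastic branching simulation), per-interval
    constrained least-squares estimation of transition, death and birth
    probabilities, a birth/death-only null model with a rejection test,
    normalized state-transition fluxes with dominant-path extraction and DOT
    export, a discretized quasi-potential (energy-level) diagram from
    steady-state occupancies, Hill-function fitting of the phospho-EGFR to
    circular-state ultrasensitive switch with response-coefficient analysis,
    and a synthetic-data generator that emulates dose- and time-dependent
    receptor signaling, pulsed and inhibitor-perturbed stimulation, replicate
    observation noise, and cell-scattering point patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
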