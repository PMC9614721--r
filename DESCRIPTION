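Package: qdfret
Title: Quantitative Analysis of Multivalent Lectin-Glycan Interactions by QD-FRET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying multivalent lectin-glycan interactions
    measured by quantum-dot FRET (Forster resonance energy transfer)
    ratiometric assays. Implements emission-spectrum background correction
    and FRET-ratio extraction, Hill-equation dissociation-constant fitting
    of fixed protein:QD-ratio titrations (including the apparent-Kd floor
    of conventional fixed-QD designs), Van't Hoff decomposition of binding
    free energy into enthalpy and entropy, stopped-flow association and
    dissociation kinetics with a linear drift term, derived-rate
    reconciliation (competition Kd' and equilibrium-consistent koff), and
    cluster-state quantification of nanoparticle assemblies from electron
    micrograph centroids. A seeded synthetic-data generator emulates every
    input so the whole pipeline is testable from known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
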