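Package: phypif
Title: Phytochrome B-PIF3 Light Signalling Kinetics and PIF3-Repressed Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and calibration of a kinetic model of the
    phytochrome B (PhyB) - PHYTOCHROME INTERACTING FACTOR 3 (PIF3) light
    signalling pathway and its control of PIF3-repressed nuclear genes
    (sigma factors, PEP-associated proteins, PRIN2) during chloroplast
    development. Implements the two-state (Pr/Pfr) photoreceptor model with
    its scaled one-variable reduction and closed-form solution, PIF3
    degradation dynamics (full three-variable system, quasi-steady-state
    reduction, fast/slow/combined closed forms), repressor-occupancy gene
    expression with ODE, quadrature, short-time and stationary solutions,
    per-gene dissociation-constant and mutant-abundance fitting from
    fold-change time courses, exact G-box/PBE-box promoter scanning with
    positional histograms, and a seeded synthetic-data generator emulating
    replicated qPCR fold-change series, decay curves and promoters with
    planted motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
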