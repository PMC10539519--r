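Package: confdesign
Title: Multistate Design and Conformational Landscape Analysis for
    Hinge-Bending Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for remodeling the open/closed conformational
    equilibrium of hinge-bending enzymes by multistate protein design.
    Provides PDB structure handling, rigid-body superposition and
    hinge-motion (screw axis) analysis, perturbation/minimization
    backbone ensemble generation, a five-term pairwise design energy
    function over rotamer libraries, exact (brute-force), dead-end
    elimination and FASTER rotamer/sequence optimizers,
    Boltzmann-weighted state-energy differences with combinatorial
    library design, nonlinear van't Hoff analysis of two-state
    equilibria from variable-temperature spectra, and steady-state
    enzyme kinetics with substrate inhibition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
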