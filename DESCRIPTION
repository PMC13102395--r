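Package: smcgo
Title: Switching Go-Model Simulations of SMC-Kleisin DNA Translocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained structure-based (Go) molecular dynamics of an
    SMC-kleisin ring complex translocating duplex DNA. Builds synthetic
    bead-resolution SMC-ScpA complexes with three nucleotide-state reference
    conformations (disengaged, engaged, V-shape), a three-site-per-nucleotide
    B-form DNA model, Debye-Huckel electrostatics, a directional
    protein-DNA hydrogen-bond potential, and a Langevin integrator with an
    ATP-cycle scheduler that switches the energy landscape between states.
    Includes trajectory statistics for DNA-segment capture and translocation
    (domain-DNA contact series, Q-scores, hinge angle, captured-loop and step
    size, outcome classification, kleisin-path asymmetry, ring threading
    parity) and a generic atomistic hydrogen-bond analysis stage
    (Baker-Hubbard detection, per-residue bond fractions, coarse-grained
    parameter derivation from geometry histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
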