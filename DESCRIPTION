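Package: fracFHR
Type: Package
Title: Fractional-Order FitzHugh-Rinzel Neuron Model: Simulation, Stability
    and Synchronization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the commensurate fractional-order FitzHugh-Rinzel
    bursting neuron model. Implements the L1 discretization of the Caputo
    derivative for arbitrary finite-dimensional vector fields with explicit
    Markov-term and memory-trace accounting, closed-form equilibrium and
    stability analysis (critical fractional exponent, chaos threshold,
    classical and fractional Hopf bifurcation structure), simulation of a
    pair of electrically coupled neurons with a similarity-function
    synchronization diagnostic, spike detection with firing-pattern
    classification, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
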