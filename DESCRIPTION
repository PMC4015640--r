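Package: ribotraffic
Title: Codon-Resolved Models of mRNA Translation: Exclusion-Process
    Simulation, Exact Markov Steady States, Mean-Field and Petri-Net
    Solvers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A multi-formalism toolkit for codon-resolved modelling of
    mRNA translation as ribosome traffic on a one-dimensional lattice.
    Provides stochastic exclusion-process (TASEP-type) simulators under
    random-sequential and parallel update rules, an exact stationary
    solver built from the Boolean event rules of the process (the
    averaged transition matrix over reachable occupancy states), the
    Heinrich-Rapoport mean-field steady state and transient ODEs, and a
    deterministic timed Petri-net comparator.  Regulatory extensions
    include slow codons, premature stop codons with readthrough, and
    negative autoregulation of initiation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
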