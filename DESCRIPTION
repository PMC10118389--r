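Package: CRISPRcoevo
Title: Stochastic and Mean-Field Models of CRISPR-Mediated
    Bacteria-Phage Coevolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the coevolution of bacteria carrying CRISPR adaptive
    immunity with lytic phages in a chemostat, using exact Gillespie and
    tau-leaping stochastic engines over an explicit reaction catalogue with
    mutating binary protospacer sequences. Provides the matching deterministic
    mean-field theory (steady states with effective immunity, the phage
    extinction threshold, dominant-balance approximations for the
    spacer-bearing fraction), clone-level analytics (establishment
    probability, large-clone extinction time, effective mutation rate, a
    self-consistent prediction for clonal diversity, speed of evolution),
    cross-reactive infection kernels, and population-analysis statistics
    (average and marginal immunity, time-shifted immunity, turnover, clan
    clustering, centre-of-mass speed and spread, Morisita-Horn similarity)
    for clone-resolved abundance time series from simulations or experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma
Suggests: testthat (>= 3.0.0), vegan, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'seqspace.R'
    'params.R'
    'sim-engine.R'
    'sim-record.R'
    'meanfield.R'
    'clonetheory.R'
    'abundance.R'
    'popanalysis.R'
    'toymodels.R'
    'workbench.R'
    'CRISPRcoevo-package.R'
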