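Package: riboloop
Title: Stochastic Simulation of Closed-Loop mRNA Translation with Ribosome Reinitiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of mRNA translation on
    circularized transcripts, modelled as a totally asymmetric simple exclusion
    process (TASEP) with extended ribosome particles, a finite transcript
    lifetime, and a reinitiation channel that returns terminating ribosomes to
    the start codon. Provides codon-specific elongation rates from decoding-rate
    tables, calibration of the de novo initiation rate to a target ribosome
    load, drivers for length sweeps, transcript-specific perturbations,
    slow-codon scans, steady-state diagnostics and whole-translatome runs, an
    exact master-equation oracle for small lattices, and synthetic fixture
    generators so everything is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    deSolve,
    Matrix,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
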