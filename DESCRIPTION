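Package: phagotrap
Title: Stochastic Motor Occupancy Models and Optical-Trap Trace Analysis
    for Bidirectional Cargo Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and analysis tools for tug-of-war transport of
    membrane-bound cargo (phagosomes) driven by opposing teams of dynein and
    kinesin motors. Implements the binomial occupancy model of motors in the
    cargo-microtubule contact zone and its joint rapid-reversal probability,
    mean-field and stochastic (Gillespie) attachment kinetics with analytic
    birth-death first-passage solutions, coin-toss Markov statistics of
    consecutive stall event pairs, an Ornstein-Uhlenbeck based synthetic
    optical-trap trace generator with full ground truth, and the stall
    detection / event pairing / rapid-reversal and tug-of-war classification
    pipeline used to analyse such traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    mclust,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
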