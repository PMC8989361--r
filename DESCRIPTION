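Package: triggerpoint
Title: Optimal Stopping Trigger Points for Ex Situ Conservation of
    Single-Population Threatened Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision support for managers of a declining single-population
    threatened species who must choose, year by year, between continuing in
    situ management and triggering an irreversible ex situ, in toto capture
    of the entire remaining population.  Fits the observed linear decline by
    ordinary least squares, propagates slope uncertainty into an
    extinction-time forecast, maintains a conjugate Beta posterior over the
    unknown annual in situ success probability, builds a finite-horizon
    Markov decision model with absorbing success and extinction states, and
    solves it by stochastic dynamic programming (backward induction of the
    Bellman equation).  Includes a receding-horizon replay of abundance
    timeseries to locate the recommended trigger year, parameter
    sensitivity sweeps, a synthetic timeseries generator with known ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
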