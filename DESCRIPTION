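Package: transitivity
Title: Non-Arrhenius Kinetics in the Arrhenius and Transitivity Planes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models, fits and classifies the temperature dependence of
    rate processes that deviate from the Arrhenius law.  Implements the
    deformed-exponential (Aquilanti-Mundim), Vogel-Fulcher-Tammann and
    Fowler-Guggenheim rate laws, apparent (Tolman) activation energies
    and their reciprocal, the transitivity function; the generalized
    transitivity power law whose exponent indexes universality classes
    (0 Arrhenius, 1 Aquilanti-Mundim, 2 Vogel-Fulcher-Tammann);
    finite-N statistical distributions and their Euler-limit convergence
    to the Poisson and Boltzmann laws; least-squares fitting of rate
    data in both planes with exponent selection, crossover-temperature
    detection and sub/super/anti-Arrhenius classification; and a seeded
    synthetic-data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
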