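Package: llpsagg
Title: Irreversible Protein Aggregation Kinetics in Phase-Separated Liquid Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates irreversible protein aggregation (primary nucleation,
    secondary nucleation, elongation) coupled to monomer partitioning between a
    liquid condensate and the surrounding dilute phase. Implements the
    two-compartment moment equations with an equilibrium-restoring monomer
    exchange flux, the fast-exchange (quasi-equilibrium) reduced model, and the
    homogeneous reference system; provides closed-form asymptotic scaling
    predictions for aggregate enrichment, depletion, and the aggregate
    partitioning ratio; and runs parameter sweeps over compartment volume and
    monomer partitioning to map regime diagrams, including the sign structure
    of the relative asymptotic aggregate concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
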