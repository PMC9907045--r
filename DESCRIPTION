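Package: gemvuln
Title: Growth-Dependent Vulnerability Detection in Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("gemvuln", "developers", email = "gemvuln@example.org",
           role = c("aut", "cre"))
Description: Detection of vulnerabilities in constraint-based metabolic
    models: chokepoint reactions, dead-end metabolites, essential
    reactions and blocked reactions, computed both from the raw flux
    bounds of the model and from growth-constrained bounds obtained by
    flux variability analysis (FVA) at a fraction gamma of the maximal
    growth rate.  Includes an SBML reader/writer, a built-in simplex
    linear-programming solver with an optional SciPy (HiGHS) backend, a
    deterministic synthetic-network generator with an independent
    brute-force oracle, a gamma-sweep driver, TSV/HTML report export
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
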