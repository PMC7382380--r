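Package: nuetrace
Title: Nitrogen Use Efficiency and Seed C:N Stoichiometry from 15N Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-balance analysis of long-term 15N labelling experiments in
    three-compartment plants (rosette, stem, seeds): per-plant nitrogen and
    tracer pools, allocation fractions, harvest index, nitrogen harvest index,
    nitrogen utilization and use efficiency, and nitrogen remobilization
    efficiency. Orthogonal (total-least-squares) regression of seed carbon on
    nitrogen concentration with the signed delta-seed-composition (DSC) trait,
    per-condition slope and intercept shifts, and genotype response vectors.
    Three-way variance decomposition with method-of-moments components,
    broad-sense heritability from expected mean squares, and contrasts of each
    stress condition against control. Includes a factorial synthetic-data
    generator with known ground truth for recovery testing, and a pipeline
    driver with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
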