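Package: tomspace
Title: Target-Space Overlap Analysis for Herbal Formulas and Drug Modules
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds toxicity-filtered, cytochrome-P450-excluded target spaces
    for traditional oriental medicine (TOM) herbal formulas and for modules of
    small-molecule drugs, scores the overlap of each (formula, drug-module)
    pair with the support statistic |X intersect Y| / |X|, aggregates supports
    across a main-indication module and its side-effect modules with a
    weighted average, and calibrates observed overlaps against a resampled
    random-target-space null with hypergeometric closed-form moments as an
    analytic check. Includes a synthetic-data generator that plants known
    overlap structure so the whole pipeline is testable without any external
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'symbols.R'
    'io.R'
    'admet.R'
    'targetspace.R'
    'support.R'
    'nullmodel.R'
    'synthetic.R'
    'pipeline.R'
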