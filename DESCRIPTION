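Package: namqtl
Title: Nested Association Mapping Simulation, Phenotype Analysis and
    Cross-Validated QTL Detection
Version: 0.1.0
Authors@R: person("NAM", "Tools", email = "namqtl@example.org",
    role = c("aut", "cre"))
Description: Simulates backcross-selfing (BC1S3) nested association
    mapping populations, aggregates multi-year plot phenotypes into
    best linear unbiased estimates with variance components and
    broad-sense heritabilities, runs a multi-family multiple-regression
    genome scan with Schwarz-criterion cofactor selection and
    Bonferroni-Holm correction, and consolidates resampling-based
    putative QTL with detection rates, explained variance and hold-out
    predictive ability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
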