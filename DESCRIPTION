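Package: screenval
Title: Test Performance Modelling for Population Genomic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the analytic and clinical validity of whole genome
    sequencing used to screen an unselected population of women for
    pathogenic BRCA1 and BRCA2 mutations. Provides a deterministic
    expected confusion-matrix model built from carrier prevalence,
    mutation-class spectrum, per-class platform sensitivity and
    horizontal gene coverage; diagnostic performance metrics
    (sensitivity, specificity, PPV, NPV); a Monte Carlo probabilistic
    sensitivity analysis over uncertain inputs; penetrance-based
    projection of expected breast-cancer counts per screening outcome;
    and a seeded individual-level cohort simulator that acts as a
    stochastic oracle for every closed-form expectation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
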