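Package: numbersense
Title: Twin and SNP-Based Heritability Analysis of Numerosity Discrimination
Version: 0.1.0
Authors@R:
    person("Numbersense", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying individual differences in the approximate
    number system ("number sense"). Scores trial-level dot-comparison
    sessions, trims reaction-time outliers with a sample-size-dependent
    moving criterion, and estimates per-subject Weber fractions by least
    squares against the standard psychophysical model. Fits classical twin
    variance-component models (saturated, ACE, AE, E) by full-information
    maximum likelihood with profile-likelihood confidence intervals, the
    four five-group sex-limitation models, and SNP-based heritability via
    a genetic relationship matrix and average-information REML. A
    synthetic-data module generates ACE-structured twin phenotypes,
    Weber-law task sessions and biallelic SNP panels with known ground
    truth, so the whole pipeline is testable without access-controlled
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
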