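Package: chd4var
Title: ACMG/AMP Interpretation of CHD4 Variants with Calibrated
    Computational Evidence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for clinical interpretation of protein-level
    variants in the chromatin remodeler CHD4: parsing of protein HGVS
    notation, calibrated mapping of REVEL scores to strength-tiered
    PP3/BP4 evidence, combination of ACMG/AMP evidence codes into
    five-tier classifications under a categorical rule table or a
    point-based system, mapping of variants onto the CHD4 domain
    architecture, exact two-by-two enrichment statistics (hypergeometric
    Fisher test and Katz odds-ratio confidence intervals) implemented
    from first principles, comparison against prior ClinVar assertions,
    and a seeded synthetic-cohort generator for end-to-end testing.
    Ships the 36-variant CHD4 study table and domain map as plain-text
    fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
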