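Package: pdcadhere
Title: Claims-Based Medication Adherence Analysis with Proportion of Days Covered
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes proportion-of-days-covered (PDC) medication adherence
    from pharmacy fill records, classifies patients as adherent at the 80%
    breakpoint, and compares intervention and control arms of a
    quasi-experimental pre/post study: unadjusted risk ratios with Katz
    log-method confidence intervals, covariate-adjusted risk ratios by
    modified Poisson regression with robust (sandwich) variance, four-level
    adherence-transition analysis with conditional pairwise risk ratios,
    absolute risk difference and number needed to treat, and baseline
    characteristic comparisons. Includes a mechanistic synthetic pharmacy
    claims generator so the whole pipeline is testable without access to
    proprietary health-plan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
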