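Package: claimsce
Title: Comparative Effectiveness Pipelines for Administrative Pharmacy and
    Medical Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for new-user comparative-effectiveness studies on
    longitudinal administrative claims: reading and validating claims
    bundles, a synthetic Medicaid-like claims generator with confounded
    treatment assignment and known true effects, index-event and inclusion
    criteria evaluation, claims-derived adherence (proportion of days
    covered), persistence, continuous-exposure and polypharmacy measures,
    inverse-probability-of-treatment weighting with standardized-difference
    balance diagnostics, and bootstrap inference for weighted mean monthly
    cost differences and Poisson rate ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
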