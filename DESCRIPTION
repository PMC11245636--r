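Package: prediagblood
Title: Pre-Diagnostic Primary-Care Blood-Test Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse general-practice blood-test activity in the
    months before a cancer diagnosis. Classifies acute phase reactant and
    red-blood-cell-index results against sex-specific reference ranges,
    builds monthly event-rate panels over the 24 pre-diagnosis months,
    estimates the diagnostic-window inflexion point with sequential
    hinge Poisson change-point models, computes rate ratios against the
    24-month baseline, and characterises cancer-type abnormality
    signatures (tested/abnormal proportions, anaemia precedence, timing
    of the first abnormal result). Includes a seeded synthetic-cohort
    generator with a known injected change point so every stage is
    testable without access to linked registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
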