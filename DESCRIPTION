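Package: cdsrules
Title: Rule-Based Clinical Decision Support for Type 2 Diabetes with
    Analytical Validation Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A declarative, chaptered rule engine for guideline-directed
    therapy of type 2 diabetes and its cardiorenal comorbidities, plus the
    machinery to validate such an engine analytically: constrained random
    generation of medically plausible single-chapter test cases, seeded
    predicted-negative mutation of engine output, baseline regression
    snapshots, blinded reviewer assignment, two-phase adjudication of
    reviewer responses, and precision / reviewer-error / accuracy metrics.
    Ships a demonstration knowledge base (not for clinical use) covering
    glycemic management, dyslipidemia, blood pressure control and
    anti-platelet therapy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
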