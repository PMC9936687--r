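Package: emstriage
Title: Concordance Between Emergency Medical Dispatch Priority and On-Scene Urgency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing telephone triage in emergency medical services
    (EMS). Implements a rule-based reference standard that dichotomises each
    ambulance dispatch into urgent or non-urgent from the on-scene record
    (paramedic assessment, transport priority, death on scene, and
    condition-plus-intervention criteria for significant treatment), compares
    it with the dispatcher's A/B/C/D priority, and reports triage test
    performance (efficiency, sensitivity, specificity, predictive values,
    over- and under-triage) with binomial confidence intervals. Includes
    per-dispatch-category summaries with chi-square, Kruskal-Wallis and
    Dunn post hoc comparisons, and a seeded synthetic dispatch-register
    generator that reproduces the category and priority structure of a
    one-month regional register, so the full pipeline runs without access
    to restricted health-register data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
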