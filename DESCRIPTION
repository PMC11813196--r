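Package: lbpcds
Title: Rule-Based Clinical Decision Support for Low Back Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-base-driven inference engine for low back pain
    (LBP) diagnosis and treatment support. Encodes patient interview and
    examination items with adaptive enabling logic, Boolean diagnosis
    rules graded on a likeliness scale with full evidence traceability,
    cross-diagnosis suppression, and diagnosis-linked treatment and
    patient-education recommendations. Ships a declarative clinical
    knowledge base, four clinical scenario fixtures plus a seeded random
    scenario generator, System Usability Scale (SUS) scoring utilities,
    and a command-line interface for validation, batch evaluation and
    interactive interviews.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
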