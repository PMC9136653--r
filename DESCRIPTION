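Package: affectner
Title: Dictionary-Based Extraction of Clinician-Recorded Affect and Mood
    from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for identifying clinician-recorded patient affect
    and mood in mental-health clinical notes.  Provides a controlled
    vocabulary of affect and mood characteristics (descriptive,
    behavioral, physiological, and comparative-change terms), a
    rule-based sentence segmenter and dictionary named-entity-recognition
    extractor, standoff annotation input/output (an eHOST-style XML
    dialect and a JSONL dialect), double-annotation agreement scoring
    with third-coder adjudication into a reference set, system
    evaluation with an error-analysis update rule that promotes
    validated system findings into the reference set, corpus prevalence
    reporting by note and provider type, and a deterministic synthetic
    note generator with gold-standard annotations for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
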