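Package: pphnlp
Title: Zero-Shot Concept Extraction and Phenotyping of Postpartum Hemorrhage
    from Discharge Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extract-then-phenotype pipeline for postpartum hemorrhage (PPH)
    built on obstetric discharge summaries. Provides a registry of 24
    PPH-related clinical concepts with prompt templates and regular-expression
    pattern sets, a chunked zero-shot extraction engine with pluggable backends
    (pattern-based, mock, generative-model adapter), numeric
    estimated-blood-loss normalization, composite PPH phenotyping and four-T
    (tone, tissue, trauma, thrombin) subtyping rule engines with ICD-9 code
    baselines, evaluation metrics including the McNemar paired test, and a
    synthetic discharge-summary generator with gold labels for offline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
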