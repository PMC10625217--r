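Package: guidescreen
Title: Automatic Literature Screening for Clinical Practice Guidelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging candidate articles during clinical practice
    guideline (CPG) development. Builds a labelled corpus from bibliographic
    records by fuzzy key-phrase screening, deduplication, journal-information
    filtering and majority-class downsampling; encodes title and abstract text
    together with journal bibliometric metrics (impact factor by year,
    CiteScore, SJR, SNIP, ranking zone, H-index); and trains a focal-loss
    classifier with batch-level inter-sample attention that ranks articles by
    the probability of being guideline-worthy. Includes a synthetic-corpus
    generator with planted keyword and journal-quality signal so the whole
    pipeline is testable offline, plus evaluation utilities (confusion-matrix
    metrics, ROC AUC, model comparison) and a ranked screening interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
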