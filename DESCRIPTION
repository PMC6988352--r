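Package: triggersieve
Title: Trigger-Based Sieve Extraction of Bacteria-Biotope Lives_In Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised, multi-pass sieve extraction of Lives_In events
    between bacteria and location mentions in biomedical text. Reads and
    writes BioNLP-ST standoff annotation (.txt/.a1/.a2), mines "context
    trigger" lemmas from corpora with dependency patterns, extracts
    intra-clause events with syntactic patterns, infers cross-clause and
    cross-sentence events by trigger transitivity inside bacteria-anchored
    context windows, filters hypothesis/negation/research-goal scopes, and
    scores predictions with the shared-task matching-similarity
    precision/recall/F1 split by intra- versus cross-sentence events. Ships
    the published trigger lexicons, transcribed worked examples with gold
    dependency parses, and a seeded template-based synthetic corpus
    generator for rule-coverage testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
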