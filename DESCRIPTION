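Package: laylink
Title: Link Medical Terms in Clinical Notes to Lay Definitions
Version: 0.1.0
Authors@R: person("laylink", "developers", role = c("aut", "cre"),
    email = "laylink@example.org")
Description: Annotates clinical note text by recognizing medical-term spans
    with a dictionary longest-match tagger (or imported external tagger
    spans), gating terms by UMLS-style semantic types, and linking them to
    lay-language definitions through a four-stage lookup with modifier
    trimming and per-word fallback. Also provides lexicon-construction
    tooling: a distantly supervised term-importance ranker with transfer
    adaptation from a small manually labeled set, and a synonym miner that
    ranks interwiki-link candidates by word-embedding cosine similarity with
    pseudo-relevance-feedback reranking. Seeded generators produce every
    synthetic input the test suite needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
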