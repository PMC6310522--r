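Package: cprex
Title: Chemical-Protein Relation Extraction with Shortest-Path LSTM Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A retrainable pipeline for extracting chemical-protein relations
    from pre-parsed biomedical text. Reads CHEMPROT-style abstract, entity and
    relation tables together with CoNLL-U dependency parses, extracts shortest
    dependency paths over word-adjacency-augmented parse graphs, and classifies
    same-sentence CHEMICAL-GENE candidate pairs into ten CPR relation classes
    plus a negative class with ensembles of LSTM networks (an SDP-only
    architecture and a combined SDP plus bidirectional-sentence architecture).
    Includes summed-confidence ensemble aggregation, union/intersection
    combination of two systems' prediction sets with min-max normalized
    confidences, micro-averaged multi-class evaluation, and a seeded synthetic
    corpus generator with a planted trigger-word rule so the full stack runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
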