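Package: clinrelex
Title: Clinical Relation Extraction for Medication and Adverse Drug Event Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A framework for identifying seven medication and adverse drug
    event (ADE) relation types in entity-annotated clinical notes, within and
    across sentence boundaries. Implements three supervised extractors over a
    common candidate-generation and evaluation protocol: a distance-bin rule
    induction baseline, a linear support vector machine over sparse TF-IDF
    n-gram, entity, semantic-type and word-representation features, and
    LSTM/BiLSTM sequence encoders with global attention trained by
    backpropagation, including a feature-augmented variant. Reads and writes
    BRAT-style standoff annotation, loads word2vec-format embedding tables and
    Brown-cluster path files, and ships a synthetic annotated-corpus generator
    that emulates the statistical structure of a private EHR benchmark
    (per-type relation frequencies, right-skewed token-distance distributions,
    intersentential relations) so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
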