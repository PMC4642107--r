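Package: bibliome
Title: Gene Regulatory Networks and Event Re-Ranking from Literature-Scale
    Event Extraction Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of biomolecular event extraction output at
    bibliome scale. Converts nested, typed biomolecular events (BioNLP
    standoff format) into a typed, directed gene regulatory network via
    rule-based event-type mapping, entity-type filtering, binding
    refactoring and per-pair edge selection, with machine-learning and
    hybrid conversion alternatives based on per-type RBF support vector
    machines. Provides a per-sentence re-ranking framework that scores
    candidate events with a pairwise ranking SVM over event, sentence
    and bibliome-wide evidence features, learns per-sentence filtering
    thresholds by regression, and includes best-case/worst-case oracle
    and random-ranking baselines. Network and event scoring (precision,
    recall, F-score, strict and relaxed Slot Error Rate) and a seeded
    synthetic bibliome generator with a planted regulatory network make
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
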