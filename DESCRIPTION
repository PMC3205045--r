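Package: chemtext
Title: Chemistry-Aware Text Mining: Named-Entity Recognition, Name
    Resolution and Experimental-Data Checking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular toolkit for mining chemistry from plain text.
    Provides a chemistry-aware tokeniser, three interchangeable named-entity
    recognisers (a regular-expression recogniser for compound serial numbers,
    a pattern recogniser built on a character n-gram naive Bayes token
    classifier, and a trainable Maximum Entropy Markov Model with Viterbi
    decoding and probabilistic span confidences), deterministic lexicon
    stages (ontology-term longest-match lookup and finite-automaton chemical
    prefix detection), dictionary-based resolution of chemical names to
    SMILES/InChI/CML structures, and a parser for stylised experimental data
    (1H/13C NMR, HRMS, elemental analysis) with consistency checks against a
    molecular formula. Ships miniature fixture lexicons and a deterministic
    synthetic-corpus generator so every stage is trainable and testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stringi,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
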