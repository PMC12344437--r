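Package: traitmine
Title: Mining Organismal Trait Mentions from Taxonomic Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for dictionary-based mining of organismal
    trait data from taxonomic treatment texts. Reads and writes offset-annotated
    documents in BioC JSON, converts between character-offset annotations and
    IOB2/CoNLL token sequences, builds taxon dictionaries from Darwin-Core-style
    checklists and curated trait dictionaries with synonym handling, performs
    gazetteer named-entity recognition with tiered normalisation to concept
    identifiers, recognises measurement and colour value mentions with a
    deterministic pattern grammar, constructs relation-extraction candidate
    windows (including none-class balancing, inline XML entity tags and
    long-range contexts) with a proximity baseline predictor, and scores
    annotations with strict and CoNLL-style chunk metrics, tolerance-based
    Cohen's kappa inter-annotator agreement, and per-document annotation
    density statistics. A seeded generator of treatment-like synthetic corpora
    with planted gold annotations makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    readxl,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
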