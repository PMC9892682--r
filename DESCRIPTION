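Package: medlex
Title: Concept-Anchored Medical Lexicon Toolkit for Spanish NLP
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and applying a concept-anchored
    medical lexicon for Spanish natural language processing. Lexical entries
    carry lemmas, inflected word forms with morphological features,
    part-of-speech categories, UMLS-style concept unique identifiers (CUIs)
    and semantic types/groups. The package reads and writes a pipe-delimited
    lexicon format and a Lexical Markup Framework (LMF) XML serialization,
    generates Spanish nominal inflection and verb conjugation, propagates
    concept identifiers across derivational and acronym/abbreviation variants,
    discovers spelling variants by edit distance, expands seed terminology by
    cosine nearest neighbours over word-vector models, pre-annotates corpora
    with dictionary matches in BRAT standoff format, and provides
    lexicon-backed lemmatization and part-of-speech tagging with per-category
    precision/recall/F1 evaluation. A synthetic-fixture generator produces
    schema-conformant toy lexicons, corpora with gold annotations, and vector
    models with planted synonym neighbourhoods so that the full pipeline is
    testable without licensed terminology content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    stringi,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
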