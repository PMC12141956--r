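Package: assocverify
Title: Ontology and Literature Verification of Generated Biomedical Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage verification of machine-generated disease-centric
    biomedical associations (disease-drug, disease-symptom, disease-gene,
    process-gene). Stage one checks each term of an association against a
    domain ontology (OBO flat files such as DOID, ChEBI, SYMP, GO) by
    normalized name and synonym matching; stage two checks the association
    itself by counting co-occurrences of the two terms in a corpus of
    literature abstracts, with period-stratified coverage statistics and
    cross-model consistency reports. Includes seeded generators for
    miniature ontologies, association sets with a controlled valid
    fraction, and corpora with planted co-occurrences, each with a full
    ground-truth log, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringi,
    stats,
    utils,
    tools,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
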