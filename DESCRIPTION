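Package: litgrn
Title: Literature-Derived Gene Regulatory Networks from Abstract Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A three-stage pipeline for extracting directed gene/protein
    regulatory interactions from publication abstracts: relevance
    pre-processing (organism filtering, sentence splitting, and two
    sentence eliminators), anonymized-pair relation classification using
    an entity-labelling schema ($GENE_AGENT#, $GENE_TARGET#, BLANK), and
    post-processing with entity-name refinement and a prior-knowledge
    weighted confidence factor CF = CF1 + K * CF2. Includes deterministic
    rule-based scorer and named-entity stubs for hermetic runs, dataset
    builders for fine-tuning external classifiers, ROC-based threshold
    selection, network export (edge table, SIF, GraphML), and a synthetic
    corpus generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    tibble,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
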