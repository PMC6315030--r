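Package: ppimutr
Title: Annotation Toolkit for Mutation Effects on Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curated annotations describing the effect of protein
    sequence changes on molecular interactions: reading, writing and
    validating the tab-delimited mutations flat file, parsing and emitting
    HGVS-style protein-change labels, quality control and remapping of
    feature coordinates across protein sequence releases, consistency
    classification of repeatedly tested mutations, mapping annotations onto
    external variant catalogues, rule-based phosphosite, affinity and
    interface-effect classifiers, dataset summary statistics, and a seeded
    synthetic-fixture generator with retrievable ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
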