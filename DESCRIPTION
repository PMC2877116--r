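Package: prokclass
Title: Sequence-Based Classification of Prokaryotic Ser/Thr Protein
    Kinase Catalytic Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Clusters prokaryotic serine/threonine protein kinase
    catalytic-domain sequences into subfamilies by greedy incremental
    clustering at an identity threshold, labels each subfamily with its
    taxonomic specificity (specific, predominant or organism-diverse at a
    rank from phylum to genus) with confirmation against homologue hit
    tables, detects kinase domains with per-sequence position-specific
    scoring matrices built from a family alignment, builds neighbor-joining
    trees with column-resampling bootstrap supports, and assigns newly
    identified kinase sequences to the established subfamilies.  Includes a
    seeded synthetic-data generator producing labeled protein families with
    planted taxonomic scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
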