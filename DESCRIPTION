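Package: litpath
Title: Literature-Mined Regulatory Pathways with Ortholog-Based Gene Ancestry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a corpus of biomedical abstracts into a curated
    regulatory pathway and dating each pathway gene's evolutionary origin.
    Abstracts are ranked against a background set by discriminating words,
    gene names and interaction words are tagged by dictionary matching,
    sentence-level co-mentions are classified into biointeraction types 1-4,
    and curated interactions are assembled into a typed, evidence-carrying
    pathway graph serialized as KGML (KEGG Markup Language). Per-gene homolog
    clusters are built by bidirectional-best-hit expansion from seed proteins
    with ortholog-group union and similarity-based verification, and each
    gene is assigned a last-common-ancestor clade on the focal
    (root-to-human) lineage together with an ancient/recent age label and an
    outgroup-ortholog flag. A synthetic-data module generates corpora with
    planted interactions, protein families with known orthology, and a
    mini-taxonomy so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    xml2,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
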