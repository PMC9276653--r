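Package: kgforge
Title: Forging Heterogeneous Biomedical Knowledge Graphs
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Toolkit for constructing a merged heterogeneous biomedical
    property graph (drugs, diseases, genes, proteins, variants, adverse
    drug reactions) from miniature emulations of public source databases.
    Parses OBO ontologies, SDF structure files, FASTA, GMT gene sets and
    annotation tables into normalized node/edge tables, applies per-source
    quality filters, resolves entities across sources via ordered mapping
    cascades (identifiers, cross-reference tables, normalized names,
    chemical structure), merges source subgraphs into a unified hetnet
    schema under a strict edge-type naming grammar, computes chemical
    structure similarity (Tanimoto/Dice on atom-pair fingerprints) to emit
    resemblance edges, validates the result, and exports clean GraphML.
    Ships a deterministic multi-source fixture generator with constructive
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite,
    ChemmineR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
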