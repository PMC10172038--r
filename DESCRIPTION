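Package: fmmap
Title: Functional Mapping Matrices for Molecular Network Embedding Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds the genes of a molecular interaction network with
    orthonormality-constrained non-negative matrix tri-factorization (NMTF)
    of a random-walk PPMI matrix, embeds functional annotations (e.g. Gene
    Ontology Biological Process terms) into the resulting gene embedding
    space, and summarises the functional organisation of the space as a
    Functional Mapping Matrix (FMM): the symmetric matrix of pairwise cosine
    distances between annotation embedding vectors. Two condition-specific
    spaces (e.g. cancer versus control tissue) are compared through their
    FMMs to detect biological functions that shift between conditions and to
    prioritise condition-related genes. Includes Lin semantic similarity over
    an OBO ontology, k-medoids based functional-organisation diagnostics,
    hypergeometric enrichment, and a synthetic scenario generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    cluster,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
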