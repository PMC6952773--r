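Package: triomix
Title: Integration of Transcriptome, Proteome and Metabolome Profiles at
    the Pathway Level
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for integrating quantitative multi-omics experiments
    (transcript, protein and metabolite tables over shared samples) into
    pathway-level evidence. Implements total-ion-count normalization,
    singlet-protein filtering, per-feature differential statistics,
    silhouette-guided K-means, competitive permutation tests for pathway
    perturbation, Fisher's combined probability test across omics layers,
    a capped-assignment ranking step that discourages repeated use of the
    same measurement by overlapping pathways, seeded t-SNE embedding with
    density-based consensus cluster extraction, hypergeometric annotation
    enrichment, an exhaustive MANOVA search over small biomarker panels,
    and construction of transcript-evidence-filtered custom proteome
    databases by six-frame translation. A synthetic-data generator with a
    planted cross-omics module makes the full pipeline testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stringr,
    jsonlite,
    cluster,
    mclust,
    Rtsne,
    Biostrings,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
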