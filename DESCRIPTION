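Package: tlscape
Title: Spatial Immune Organization Around Pancreatic Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing immune organization around
    pancreatic precursor (PanIN) and invasive (PDAC) lesions from multiplexed
    imaging and spatial transcriptomics. Provides marker-gated cell
    phenotyping, per-region immune cell densities with rank-based tests,
    nearest-neighbour interaction and top-2 neighbour contact matrices,
    detection and maturity classification of tertiary lymphoid structures
    (TLS) with a 250 um lesion-association rule, hex-lattice spot
    neighbourhood expansion, sparse non-negative matrix factorization of
    spot-level expression, a fractional-expression pattern-marker statistic
    that allows genes to mark multiple latent patterns, bin-matched module
    scoring, and preranked permutation GSEA. A synthetic-data module plants
    known ground truth (cell maps with TLS aggregates, hex-lattice counts
    with latent patterns) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
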