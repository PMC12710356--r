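Package: grdiscover
Title: Discovery of Prokaryotic Global Regulators from Protein Embeddings and Promoter Motif Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering prokaryotic global
    regulators (GRs). Provides a binary GR classifier head (a small
    transformer encoder with analytic gradients) over frozen per-residue
    protein-embedding backends, a training protocol with per-epoch negative
    subsampling and hard-negative weighting of transcription-factor decoys,
    exact p-value position-weight-matrix scanning of promoter windows with a
    three-tier hit filter, hierarchical core-regulon inference, directed
    GR-GR regulatory network construction, and a deterministic synthetic
    fixture generator (labelled protein families, motifs, and annotated
    genomes with planted binding sites) so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
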