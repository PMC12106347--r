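Package: ciliome
Title: Cilia-Associated Gene Analysis for Ciliates with Variant Genetic Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing cilia-associated genes in hypotrich ciliates
    from macronuclear genome and transcriptome assemblies. Implements open
    reading frame discovery under reassigned genetic codes (e.g. the Euplotes
    UGA-to-cysteine code), telomere-aware nanochromosome contig filtering,
    detection of programmed ribosomal frameshift (+1/+2 PRF) genes by
    stop-codon excision and C-terminal extension testing, protein similarity
    search with gene-family assignment and cross-species conservation
    partitioning, twelve topological centrality scores with consensus hub-gene
    ranking for protein-protein interaction networks, qPCR relative
    quantification (2^-ddCq), and swimming-track kinematics. A seeded
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Annotation, Network, GenePrediction
RoxygenNote: 7.3.3
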