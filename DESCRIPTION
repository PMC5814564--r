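Package: g4wga
Title: G-Quadruplex Cluster Detection from Ligand-Stalled Whole-Genome
    Amplification Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies G-quadruplex (G4) clusters from paired
    high-throughput sequencing libraries of whole-genome amplification
    products prepared with and without a G4-stabilising ligand. A
    G4-bound ligand arrests the strand-displacing polymerase, so regions
    dense in quadruplex-forming sequences are depleted of reads in the
    ligand library. The package bins mapped reads into fixed genomic
    windows, computes per-window ligand/control depletion ratios with
    Fisher's exact tests, scores putative quadruplex-forming sequences
    with a G4Hunter implementation, derives calling thresholds from
    positive and negative control gene sets, calls clusters by the
    conjunction of PQS density, external G4-seq support and read
    depletion, extracts ligand-inducible clusters, and tests overlap
    enrichment with transcription start sites. A seeded synthetic-data
    generator with planted ground truth makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
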