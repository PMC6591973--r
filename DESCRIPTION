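Package: aspfam
Title: Genome-Wide Characterization of Plant Aspartic-Protease Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide characterization of
    pepsin-like aspartic-protease (AP) gene families in plants. Implements
    rule-based identification of complete-domain family members from CDS and
    protein sequences (perfect-ORF checks, D[TS]G catalytic-motif spacing,
    category A/B/C assignment by plant-specific-insert and nucellin motifs,
    molecular weights, majority-vote localization), neighbor-joining
    phylogenies with bootstrap support, exon/intron structure statistics,
    tandem and segmental duplication detection with Nei-Gojobori (1986)
    Ka/Ks estimation and molecular-clock dating, IUPAC degenerate scanning
    of 3-kb promoters for secondary-cell-wall cis-elements, N-glycosylation
    sequon analysis, and expression-matrix filtering and clustering. A
    synthetic-genome generator with planted ground truth makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, SequenceMatching, GeneFamilies
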