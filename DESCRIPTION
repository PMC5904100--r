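Package: amoatax
Title: Curation, Taxonomy and Molecular Signatures for Archaeal amoA Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for marker-gene databases of ammonia-oxidising
    archaea (AOA), built around the amoA gene. It curates raw nucleotide
    records into in-frame, stop-free fragments on a common 591-column coding
    frame; assembles an abundance- and identity-corroborated reference set and
    flags two-parent (bimeric) PCR chimeras with a divergence plus vote-score
    decision rule; clusters curated genes into OTUs by average-neighbour
    (average-linkage) agglomeration; derives a deterministic multilevel
    taxonomy from dual branch-support thresholds (ultrafast bootstrap and
    SH-aLRT); selects consensus phylogenies by internode and tree certainty
    and checks clade congruence against reference trees; computes per-gene
    base-composition and codon-usage signatures (GC, purine, effective number
    of codons, global codon adaptation index) with per-OTU deviation
    summaries; and profiles hierarchical habitat annotations with level-wise
    fraction rules and Krona-style exports. A seeded synthetic-data generator
    produces every pipeline input with known ground truth, so the whole
    pipeline is testable end to end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
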