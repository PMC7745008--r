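Package: ProbeTiler
Title: Probe Design for Highly Multiplexed Fluorescence In Situ Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs oligonucleotide probe libraries for highly multiplexed
    fluorescence in situ hybridization (FISH) experiments, including
    chromatin tracing, RNA MERFISH, and sequential single-molecule RNA FISH.
    Target sequences are tiled with a sliding window and candidate oligos
    are filtered on nearest-neighbor melting temperature, GC content,
    homopolymer runs, hairpin stems, and cross-hybridization against the
    growing probe pool. Specificity is screened with a built-in strand-aware
    k-mer seed-and-extend search (or an optional BLAST+ backend) against
    genome and spliced/unspliced transcriptome databases. For MERFISH, a
    140-word length-16 weight-4 Hamming-distance-4 barcode codebook is
    generated and assigned to genes with expression-aware rearrangement to
    reduce bit sharing among highly expressed genes. Assembled template
    oligos or primary probes (primers, readout sequences, targeting region)
    are exported as FASTA and CSV tables. A deterministic synthetic
    genome/transcriptome generator supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
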