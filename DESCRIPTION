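Package: fungedit
Title: Genome-Wide Detection and Characterization of Fungal A-to-I mRNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A strand-aware pipeline for discovering adenosine-to-inosine
    (A-to-I) mRNA editing from RNA-seq/DNA comparisons in fungal genomes,
    modelled on the perithecium-specific editing system of filamentous
    ascomycetes. Provides a synthetic-data generator with planted editing
    truth, pileup construction from strand-specific paired-end alignments
    with PCR-duplicate removal, a stringent RNA-DNA variant filter cascade,
    an equal-error-rate false-discovery-rate estimator, codon-consequence
    annotation including stop-loss and stop-retained editing, detection of
    pseudogene-like genes whose misannotated introns conceal editable
    in-frame UAG stops, nucleotide-context preference statistics against a
    random-adenosine control, RNA secondary-structure element classification
    of edited sites with minimum-free-energy folding, and stage-specific
    expression quantification (FPKM/CPM).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
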