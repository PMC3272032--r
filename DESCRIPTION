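Package: alutrace
Title: Detection and Epigenetic Characterization of Recent Alu Insertions
    from Alu-Anchored Bisulfite PCR Reads
Version: 0.1.0
Authors@R:
    person("alutrace", "maintainers", email = "alutrace@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering evolutionarily recent Alu
    element insertions from Alu-anchored bisulfite PCR sequence reads and
    for characterizing their retrotransposition hallmarks and CpG
    methylation. Reads are Alu-masked, their 5' genomic flanks mapped to an
    in-silico bisulfite-converted reference with a multi-cycle
    decreasing-word-size seed-and-extend strategy, junctions classified
    against a repeat annotation, candidate insertions clustered and
    cross-referenced with known polymorphic-insertion tables, and target
    site duplications, endonuclease cleavage motifs, poly-A tails and AluY
    subfamilies annotated. Per-CpG methylation is called from the bisulfite
    reads and summarized by element region (A box, B box, arms, flanks),
    including hemizygous allele comparisons. A synthetic-data module
    generates toy references, target-primed reverse transcription insertion
    events, methylomes and bisulfite amplicon reads with known truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
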