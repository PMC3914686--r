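Package: svpopgen
Title: Population Genomics of Large Indel Structural Variants from
    Paired-End Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for discovering large
    (>= 1 kb) deletion polymorphisms segregating among inbred lines from
    discordant paired-end read alignments, and for population-genetic
    analysis of the resulting call set.  Includes a discordant read-pair
    classifier and two-dimensional single-linkage clusterer, a filter
    cascade (reference-accession, minimum size, deletion read-depth,
    discordant-read density, and coverage-band filters), a pileup-style
    SNP caller for homozygous lines, a fixed-segregating-sites Kingman
    coalescent simulator for neutral envelopes of Tajima's D and
    normalized Fay and Wu's H, Monte-Carlo allele-frequency sampling
    error, intra-allelic diversity based allele-age estimation with a
    diffusion inversion to population-scaled selection coefficients,
    annotation-overlap and enrichment analyses, a joint D/H positive
    selection scan, and a synthetic-data generator that plants deletions
    and SNPs in simulated inbred genomes with controlled alignment noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
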