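Package: splicecomb
Title: Splice-Site Dinucleotide Combination Analysis Across Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and classification of intron border dinucleotides
    (canonical GT-AG, major non-canonical GC-AG and AT-AC, and minor
    non-canonical combinations) from a genome sequence and its annotation,
    validation of annotated splice sites against RNA-Seq coverage evidence,
    splice-site usage and expression statistics, intron frame and in-frame
    stop-codon analysis, Shannon diversity and GC statistics of splice-site
    spectra, cross-species conservation scoring of combination strings, and
    overlap of sequence variants with splice-site positions. Includes a
    synthetic-data generator that emits genomes, annotations, coverage
    evidence, count tables and variant sets with known ground truth, so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    S4Vectors,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
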