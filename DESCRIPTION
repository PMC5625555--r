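Package: cagescanr
Title: Processing of Paired-End CAGEscan Libraries into Promoter-Seeded
    Transcript Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to process barcoded paired-end 5' CAGE (CAGEscan)
    sequencing libraries: demultiplexing, trimming and contaminant
    filtering of raw read pairs; proper-pair classification of genome
    alignments; conversion of proper pairs to BED12 records scored by
    summed mapping quality; coordinate-identity deduplication;
    assembly of promoter-seeded CAGEscan clusters and cross-library
    meta-clusters; per-library QC accounting as subject-predicate-object
    triples; annotation of pair start sites against promoter and exon
    intervals; and inter-library Jaccard similarity for replicate
    identification. A self-contained synthetic-experiment generator
    (genome, transcript models, seed peaks, FASTQ, SAM, ground truth)
    makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
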