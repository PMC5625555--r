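# Fixture builders shared across tests.  Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# one aligned pair row in the shape produced by read_pairs_from_sam()
aligned_pair <- function(read_id = "r1", chrom = "chr1",
                         s1 = 100L, e1 = 136L, strand1 = "+",
                         s2 = 500L, e2 = 530L, strand2 = "-",
                         mapq1 = 20L, mapq2 = 30L,
                         mapped1 = TRUE, mapped2 = TRUE,
                         cigar1 = NULL, cigar2 = NULL,
                         chrom2 = chrom) {
  data.frame(
    read_id = read_id,
    chrom1 = chrom, start1 = s1, end1 = e1, strand1 = strand1,
    mapq1 = mapq1, mapped1 = mapped1, flag1 = 0x41L,
    cigar1 = if (is.null(cigar1)) paste0(e1 - s1, "M") else cigar1,
    chrom2 = chrom2, start2 = s2, end2 = e2, strand2 = strand2,
    mapq2 = mapq2, mapped2 = mapped2, flag2 = 0x81L,
    cigar2 = if (is.null(cigar2)) paste0(e2 - s2, "M") else cigar2,
    stringsAsFactors = FALSE)
}

# one BED12 pair record
bed12_row <- function(chrom = "chr1", start = 100L, end = 530L,
                      name = "r1", score = 50, strand = "+",
                      tss = start, blockSizes = NULL, blockStarts = NULL) {
  if (is.null(blockSizes)) {
    blockSizes <- as.character(end - start)
    blockStarts <- "0"
  }
  nb <- length(strsplit(blockSizes, ",")[[1]])
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = as.numeric(score), strand = strand,
             thickStart = tss, thickEnd = tss + 1L, itemRgb = "0",
             blockCount = nb, blockSizes = blockSizes,
             blockStarts = blockStarts, stringsAsFactors = FALSE)
}

seed_row <- function(chrom = "chr1", start = 95L, end = 105L,
                     name = "s1", strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = 0, strand = strand, stringsAsFactors = FALSE)
}

# small, fast simulation settings
small_sim_config <- function(seed, n_transcripts = 5L, ...) {
  sim_config(seed = seed, n_transcripts = n_transcripts,
             genome_length = n_transcripts * 3000L,
             pairs_per_transcript = c(8L, 15L), ...)
}

# raw read pair (FASTQ-side) builder
raw_pair <- function(read_id = "p1", seq1, seq2) {
  data.frame(read_id = read_id, seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
             seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
             stringsAsFactors = FALSE)
}

# brute-force Hamming scan: does q match anywhere in r with <= k mismatches?
brute_match <- function(q, r, k, both_strands = FALSE) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  scan1 <- function(q, r) {
    if (nchar(q) > nchar(r)) { tmp <- q; q <- r; r <- tmp }
    nq <- nchar(q); nr <- nchar(r)
    qs <- strsplit(q, "")[[1]]
    for (off in 0:(nr - nq)) {
      w <- strsplit(substr(r, off + 1, off + nq), "")[[1]]
      if (sum(w != qs) <= k) return(TRUE)
    }
    FALSE
  }
  scan1(q, r) || (both_strands && scan1(rc(q), r))
}
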