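#' Read paired FASTQ files into a pair table
#'
#' Reads two matched FASTQ files (read1 = CAGE/5' read, read2 = CAGEscan
#' read) and joins them record-by-record into one data frame.  Records are
#' matched positionally; read identifiers (the FASTQ header up to the first
#' whitespace) must agree between the two files.
#'
#' @param r1_path Path to the read1 (CAGE) FASTQ file.
#' @param r2_path Path to the read2 (CAGEscan) FASTQ file.
#' @return A data frame with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("read1 and read2 files have different record counts (",
         length(r1), " vs ", length(r2), ")")
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  if (!identical(id1, id2))
    stop("read identifiers differ between mates; files must be in the ",
         "same order")
  data.frame(
    read_id = id1,
    seq1  = as.character(r1),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    seq2  = as.character(r2),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a pair table to two FASTQ files
#'
#' @param pairs Data frame as returned by [read_fastq_pairs()].
#' @param r1_path,r2_path Output paths for the two mates.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  stopifnot(all(c("read_id", "seq1", "qual1", "seq2", "qual2") %in%
                  names(pairs)))
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- pairs$read_id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$seq1, pairs$qual1, r1_path)
  write_one(pairs$seq2, pairs$qual2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
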