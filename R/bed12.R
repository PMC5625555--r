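BED12_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                "thickStart", "thickEnd", "itemRgb",
                "blockCount", "blockSizes", "blockStarts")

empty_bed12 <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = numeric(0), strand = character(0),
             thickStart = integer(0), thickEnd = integer(0),
             itemRgb = character(0), blockCount = integer(0),
             blockSizes = character(0), blockStarts = character(0),
             stringsAsFactors = FALSE)
}

split_ints <- function(x) lapply(strsplit(x, ","), as.integer)

# absolute-coordinate IRanges for one BED12 row's blocks
row_blocks <- function(row) {
  sizes <- split_ints(row$blockSizes)[[1]]
  starts <- split_ints(row$blockStarts)[[1]]
  IRanges::IRanges(start = row$start + starts, width = sizes)
}

# IRanges (absolute, 0-based starts stored as 1-based IRanges internally
# via start+1) are avoided: we keep 0-based arithmetic in plain integers
# and only use IRanges for the set algebra, with start = 0-based start + 1.
blocks_to_iranges <- function(start0, sizes) {
  IRanges::IRanges(start = start0 + 1L, width = sizes)
}

iranges_to_bed_blocks <- function(ir, chrom_start0) {
  ir <- IRanges::reduce(ir)             # sorted, merged
  s0 <- IRanges::start(ir) - 1L
  list(count = length(ir),
       sizes = paste(IRanges::width(ir), collapse = ","),
       starts = paste(s0 - chrom_start0, collapse = ","))
}

#' Convert proper aligned pairs to BED12 pair records
#'
#' Each properly paired CAGE/CAGEscan alignment becomes one BED12 record:
#' the span covers both mates, the score is the sum of the two mapping
#' qualities, the strand is the CAGE mate's strand, the thick interval
#' marks the 1-bp transcription start site (the CAGE mate's 5' base), and
#' the blocks are the union of both mates' reference-consuming CIGAR
#' segments (split at N operations, overlap/adjacency merged).
#'
#' @param pairs Pair table from [read_pairs_from_sam()]; all rows must
#'   classify as Proper.
#' @param policy A [proper_pair_policy()] used to enforce the contract.
#' @return A BED12 data frame, one row per pair.
#' @export
pair_to_bed12 <- function(pairs, policy = proper_pair_policy()) {
  if (nrow(pairs) == 0L) return(empty_bed12())
  if (!all(classify_pair(pairs, policy) == "Proper"))
    stop("pair_to_bed12 requires properly paired input; run classify_pair")
  ref_ops <- c("M", "=", "X", "D")
  b1 <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    pairs$cigar1, pos = pairs$start1 + 1L, ops = ref_ops,
    drop.empty.ranges = TRUE, reduce.ranges = TRUE)
  b2 <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    pairs$cigar2, pos = pairs$start2 + 1L, ops = ref_ops,
    drop.empty.ranges = TRUE, reduce.ranges = TRUE)
  n <- nrow(pairs)
  out <- vector("list", n)
  tss <- ifelse(pairs$strand1 == "+", pairs$start1, pairs$end1 - 1L)
  for (i in seq_len(n)) {
    u <- IRanges::reduce(c(b1[[i]], b2[[i]]))
    cs <- IRanges::start(u)[1L] - 1L
    ce <- IRanges::end(u)[length(u)]
    out[[i]] <- data.frame(
      chrom = pairs$chrom1[i], start = cs, end = ce,
      name = pairs$read_id[i],
      score = as.numeric(pairs$mapq1[i] + pairs$mapq2[i]),
      strand = pairs$strand1[i],
      thickStart = tss[i], thickEnd = tss[i] + 1L,
      itemRgb = "0",
      blockCount = length(u),
      blockSizes = paste(IRanges::width(u), collapse = ","),
      blockStarts = paste(IRanges::start(u) - 1L - cs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a BED12 file
#'
#' @param path Tab-delimited 12-column BED file (0-based, half-open).
#' @return BED12 data frame (block columns kept as comma strings).
#' @export
read_bed12 <- function(path) {
  if (file.size(path) == 0) return(empty_bed12())
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character",
                                        "integer", "integer", "character",
                                        "integer", "character", "character"))
  names(d) <- BED12_COLS
  d
}

#' Write a BED12 data frame
#'
#' @param bed BED12 data frame.
#' @param path Output path.
#' @param strict_bed Clamp scores into the BED-valid range 0..1000
#'   (default TRUE).  Pair counts and library counts can legitimately
#'   exceed 1000; pass FALSE to write them unclamped.
#' @return Invisibly, the path.
#' @export
write_bed12 <- function(bed, path, strict_bed = TRUE) {
  stopifnot(identical(names(bed), BED12_COLS))
  if (strict_bed) bed$score <- pmin(pmax(bed$score, 0), 1000)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Tab-delimited 6-column BED file.
#' @return Data frame chrom/start/end/name/score/strand.
#' @export
read_bed6 <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character"))
  names(d) <- c("chrom", "start", "end", "name", "score", "strand")
  d
}

#' Write a BED6 data frame
#'
#' @param bed Data frame chrom/start/end/name/score/strand.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed6 <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score",
                             "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate BED12 block structure
#'
#' Checks every record: positive sizes, block count consistent with the
#' size/start lists, blocks sorted and non-overlapping, first block flush
#' with chromStart and last block flush with chromEnd.
#'
#' @param bed BED12 data frame.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validate_bed12 <- function(bed) {
  for (i in seq_len(nrow(bed))) {
    sizes <- split_ints(bed$blockSizes[i])[[1]]
    starts <- split_ints(bed$blockStarts[i])[[1]]
    ok <- length(sizes) == bed$blockCount[i] &&
      length(starts) == bed$blockCount[i] &&
      all(sizes > 0L) && !is.unsorted(starts, strictly = TRUE) &&
      starts[1L] == 0L &&
      starts[length(starts)] + sizes[length(sizes)] ==
        bed$end[i] - bed$start[i] &&
      all(utils::head(starts + sizes, -1L) <= utils::tail(starts, -1L)) &&
      bed$start[i] < bed$end[i]
    if (!ok)
      stop("invalid BED12 block structure in record ", i,
           " (", bed$name[i], ")")
  }
  invisible(TRUE)
}
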