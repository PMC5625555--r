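#' Proper-pair acceptance policy
#'
#' @param max_span Maximum outer span (bp) between the mates' extreme
#'   coordinates, inclusive.  Default 2,000,000 — wide enough for the two
#'   mates of a pair to fall on different exons of most genes.
#' @param require_head_to_head Require inward-facing (FR) orientation:
#'   opposite strands with the plus-strand mate starting at or left of the
#'   minus-strand mate.  Default TRUE.
#' @return A list of class `proper_pair_policy`.
#' @export
proper_pair_policy <- function(max_span = 2000000L,
                               require_head_to_head = TRUE) {
  max_span <- as.numeric(max_span)
  if (max_span <= 0) stop("max_span must be positive")
  structure(list(max_span = max_span,
                 require_head_to_head = isTRUE(require_head_to_head)),
            class = "proper_pair_policy")
}

#' Read paired alignments from SAM/BAM
#'
#' Joins primary alignments by read name and first/second-in-pair flags
#' into one row per pair.  Mate 1 is the CAGE (5') read, mate 2 the
#' CAGEscan read.  SAM 1-based positions are converted to 0-based
#' half-open intervals; ends come from CIGAR reference consumption.
#' Secondary and supplementary alignments (0x100/0x800) are dropped.
#'
#' @param path SAM or BAM file.
#' @return Data frame with one row per pair: `read_id`, then per mate
#'   `chrom`, `start`, `end`, `strand`, `mapq`, `mapped`, `flag`, `cigar`
#'   (suffixed 1/2).
#' @export
read_pairs_from_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  if (!any(primary))
    return(empty_pair_table())
  d <- data.frame(read_id = res$qname[primary],
                  flag = flag[primary],
                  chrom = as.character(res$rname[primary]),
                  pos = res$pos[primary],
                  mapq = res$mapq[primary],
                  cigar = res$cigar[primary],
                  strand = as.character(res$strand[primary]),
                  stringsAsFactors = FALSE)
  d$mapped <- bitwAnd(d$flag, 0x4L) == 0L
  if (any(bitwAnd(d$flag, 0x1L) == 0L))
    stop("unpaired alignment record(s): ",
         paste(utils::head(d$read_id[bitwAnd(d$flag, 0x1L) == 0L], 3),
               collapse = ", "))
  d$start <- ifelse(d$mapped, d$pos - 1L, NA_integer_)
  width <- rep(NA_integer_, nrow(d))
  ok <- d$mapped & !is.na(d$cigar)
  if (any(ok))
    width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(d$cigar[ok])
  d$end <- d$start + width
  d$chrom[!d$mapped] <- NA_character_
  d$strand[!d$mapped] <- NA_character_
  first <- bitwAnd(d$flag, 0x40L) != 0L
  second <- bitwAnd(d$flag, 0x80L) != 0L
  if (any(first & second) || any(!first & !second))
    stop("records must be flagged first or second in pair, exclusively")
  m1 <- d[first, , drop = FALSE]
  m2 <- d[second, , drop = FALSE]
  i <- match(m1$read_id, m2$read_id)
  if (anyNA(i) || nrow(m1) != nrow(m2))
    stop("orphan mate(s): read ids not paired across first/second records")
  m2 <- m2[i, , drop = FALSE]
  out <- data.frame(
    read_id = m1$read_id,
    chrom1 = m1$chrom, start1 = m1$start, end1 = m1$end,
    strand1 = m1$strand, mapq1 = m1$mapq, mapped1 = m1$mapped,
    flag1 = m1$flag, cigar1 = m1$cigar,
    chrom2 = m2$chrom, start2 = m2$start, end2 = m2$end,
    strand2 = m2$strand, mapq2 = m2$mapq, mapped2 = m2$mapped,
    flag2 = m2$flag, cigar2 = m2$cigar,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

empty_pair_table <- function() {
  data.frame(read_id = character(0),
             chrom1 = character(0), start1 = integer(0), end1 = integer(0),
             strand1 = character(0), mapq1 = integer(0),
             mapped1 = logical(0), flag1 = integer(0), cigar1 = character(0),
             chrom2 = character(0), start2 = integer(0), end2 = integer(0),
             strand2 = character(0), mapq2 = integer(0),
             mapped2 = logical(0), flag2 = integer(0), cigar2 = character(0),
             stringsAsFactors = FALSE)
}

#' Test proper (head-to-head) pairing
#'
#' TRUE iff the mates share a reference, lie on opposite strands with the
#' plus-strand mate starting at or left of the minus-strand mate
#' (inward/FR orientation; equal starts accepted), and the outer span
#' `max(end) - min(start)` does not exceed `policy$max_span` (inclusive).
#' Both mates must be mapped.
#'
#' @param pairs Pair table from [read_pairs_from_sam()] (vectorised).
#' @param policy A [proper_pair_policy()].
#' @return Logical vector, one value per pair.
#' @export
is_proper_pair <- function(pairs, policy = proper_pair_policy()) {
  if (!all(pairs$mapped1 & pairs$mapped2))
    stop("is_proper_pair requires both mates mapped; ",
         "route unmapped pairs to NonAligned first")
  same_ref <- pairs$chrom1 == pairs$chrom2
  opp <- pairs$strand1 != pairs$strand2
  plus_start <- ifelse(pairs$strand1 == "+", pairs$start1, pairs$start2)
  minus_start <- ifelse(pairs$strand1 == "-", pairs$start1, pairs$start2)
  orient <- if (policy$require_head_to_head) {
    opp & plus_start <= minus_start
  } else rep(TRUE, nrow(pairs))
  span <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
  same_ref & orient & span <= policy$max_span
}

#' Classify aligned pairs
#'
#' Assigns exactly one label per pair: `NonAligned` if either mate is
#' unmapped, else `NonProper` if [is_proper_pair()] fails, else `Proper`.
#'
#' @param pairs Pair table from [read_pairs_from_sam()].
#' @param policy A [proper_pair_policy()].
#' @return Factor with levels `NonAligned`, `NonProper`, `Proper`.
#' @export
classify_pair <- function(pairs, policy = proper_pair_policy()) {
  n <- nrow(pairs)
  lab <- rep("NonAligned", n)
  both <- pairs$mapped1 & pairs$mapped2
  if (any(both)) {
    proper <- is_proper_pair(pairs[both, , drop = FALSE], policy)
    lab[both] <- ifelse(proper, "Proper", "NonProper")
  }
  factor(lab, levels = c("NonAligned", "NonProper", "Proper"))
}
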