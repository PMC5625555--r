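LEDGER_CATEGORIES <- c("Total", "Unextracted", "Artefacts", "rDNA",
                       "NonAligned", "NonProper", "Duplicates",
                       "CAGEscanPairs")

#' Build a per-library QC ledger
#'
#' The ledger accounts for every input read pair once: the six rejection
#' categories plus the surviving CAGEscan pairs partition the total.
#'
#' @param library_id Library identifier.
#' @param total,unextracted,artefacts,rdna,non_aligned,non_proper,duplicates,cagescan_pairs
#'   Category counts.  `total` may be omitted (it is then computed).
#' @return A list of class `qc_ledger` with `library_id` and named
#'   integer `counts`.
#' @export
qc_ledger <- function(library_id, unextracted = 0L, artefacts = 0L,
                      rdna = 0L, non_aligned = 0L, non_proper = 0L,
                      duplicates = 0L, cagescan_pairs = 0L,
                      total = NULL) {
  counts <- c(Unextracted = as.integer(unextracted),
              Artefacts = as.integer(artefacts),
              rDNA = as.integer(rdna),
              NonAligned = as.integer(non_aligned),
              NonProper = as.integer(non_proper),
              Duplicates = as.integer(duplicates),
              CAGEscanPairs = as.integer(cagescan_pairs))
  if (is.null(total)) total <- sum(counts)
  counts <- c(Total = as.integer(total), counts)
  led <- structure(list(library_id = library_id, counts = counts),
                   class = "qc_ledger")
  validate_ledger(led)
  led
}

validate_ledger <- function(ledger) {
  counts <- ledger$counts
  stopifnot(identical(names(counts), LEDGER_CATEGORIES))
  s <- sum(counts[-1L])
  if (counts[["Total"]] != s)
    stop("ledger partition violated for ", ledger$library_id,
         ": Total = ", counts[["Total"]],
         " but categories sum to ", s)
  invisible(TRUE)
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat("QC ledger for library", x$library_id, "\n")
  print(x$counts)
  invisible(x)
}

#' Write a QC ledger as subject-predicate-object triples
#'
#' One tab-delimited line per category:
#' `library_id <TAB> category <TAB> count`, in fixed category order
#' (Total, Unextracted, Artefacts, rDNA, NonAligned, NonProper,
#' Duplicates, CAGEscanPairs).  The partition invariant is re-checked
#' before writing; a violated ledger is refused.
#'
#' @param ledger A [qc_ledger()].
#' @param path Output path; an existing file is appended to when
#'   `append = TRUE`.
#' @param append Append instead of overwrite (default FALSE).
#' @return Invisibly, the path.
#' @export
write_ledger <- function(ledger, path, append = FALSE) {
  validate_ledger(ledger)
  lines <- paste(ledger$library_id, names(ledger$counts),
                 ledger$counts, sep = "\t")
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read QC ledgers from a triples file
#'
#' @param path Triples TSV written by [write_ledger()].
#' @return Named list of `qc_ledger` objects, one per library id.
#' @export
read_ledger <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("library_id", "category", "count"))
  out <- lapply(split(d, d$library_id), function(x) {
    counts <- stats::setNames(as.integer(x$count), x$category)
    led <- structure(list(library_id = x$library_id[1],
                          counts = counts[LEDGER_CATEGORIES]),
                     class = "qc_ledger")
    validate_ledger(led)
    led
  })
  out[unique(d$library_id)]
}

ann_granges <- function(bed) {
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = ifelse(bed$strand == ".", "*", bed$strand))
}

#' Classify pair start sites against promoter and exon annotations
#'
#' Each record's TSS base is tested for membership in a same-strand (or
#' unstranded) promoter interval, then exon interval, with strict
#' precedence Promoter > Exon > Other.
#'
#' @param bed BED12 pair records (TSS = thickStart).
#' @param promoters,exons BED6 data frames (strand `.` matches both).
#' @return Factor with levels Promoter, Exon, Other.
#' @export
classify_start <- function(bed, promoters, exons) {
  n <- nrow(bed)
  lab <- rep("Other", n)
  if (n == 0L)
    return(factor(lab, levels = c("Promoter", "Exon", "Other")))
  tss <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$thickStart + 1L, width = 1L),
    strand = bed$strand)
  hit <- function(ann) {
    if (nrow(ann) == 0L) return(logical(n))
    IRanges::overlapsAny(tss, ann_granges(ann))
  }
  lab[hit(exons)] <- "Exon"
  lab[hit(promoters)] <- "Promoter"
  factor(lab, levels = c("Promoter", "Exon", "Other"))
}

#' Seed peaks detected by a library
#'
#' @param clusters BED12 cluster data frame from one library.
#' @param min_pairs Minimum member-pair count for a seed to count as
#'   detected (default 1).
#' @return Character vector of seed names.
#' @export
detected_peaks <- function(clusters, min_pairs = 1L) {
  clusters$name[clusters$score >= min_pairs]
}

#' Jaccard similarity matrix between libraries
#'
#' J(A, B) = |A intersect B| / |A union B| over the detected-peak sets;
#' J is defined as 0 when both sets are empty.
#'
#' @param peak_sets Named list: library id -> character vector of
#'   detected seed names.  At least two libraries.
#' @return Symmetric numeric matrix with library ids as dimnames.
#' @export
jaccard_matrix <- function(peak_sets) {
  if (length(peak_sets) < 2L)
    stop("need at least two libraries for a similarity matrix")
  ids <- names(peak_sets)
  sets <- lapply(peak_sets, unique)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i)) {
      u <- length(union(sets[[i]], sets[[j]]))
      m[i, j] <- m[j, i] <-
        if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  m
}

#' Most similar library (replicate candidate)
#'
#' Returns the library with the highest off-diagonal Jaccard similarity
#' to `library_id`; ties break lexicographically.
#'
#' @param matrix Similarity matrix from [jaccard_matrix()].
#' @param library_id Row to query.
#' @return A library id.
#' @export
best_match <- function(matrix, library_id) {
  if (nrow(matrix) < 2L) stop("similarity matrix has a single library")
  row <- matrix[library_id, ]
  row <- row[setdiff(names(row), library_id)]
  cand <- names(row)[row == max(row)]
  sort(cand)[1L]
}
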