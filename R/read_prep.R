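#' Configuration for raw read preparation
#'
#' Bundles the parameters of the demultiplex/trim/filter stage.  The CAGE
#' read (read1) starts with a sample barcode followed by the
#' template-switching linker; both are removed by trimming `r1_trim` bases.
#' The CAGEscan read (read2) starts with `r2_trim` random-primer bases.
#'
#' @param barcode Sample barcode expected as the read1 prefix
#'   (default `"GCTATA"`).
#' @param linker Linker pattern following the barcode; `N` matches any base.
#'   Its length must equal `r1_trim - nchar(barcode)`.  Default `"NNN"`.
#' @param r1_trim Number of bases trimmed from read1 (default 9:
#'   6-nt barcode + 3-nt linker).
#' @param r2_trim Number of bases trimmed from read2 (default 6,
#'   the random-primer bases).
#' @param artefacts Named character vector of artefact sequences (empty
#'   constructs, primers), or a FASTA path.
#' @param rdna Named character vector holding the ribosomal DNA reference,
#'   or a FASTA path.
#' @param max_mismatch Number of mismatches tolerated when matching the
#'   barcode and when matching reads against artefact/rDNA references
#'   (default 0 = exact).
#' @param low_complexity Mono-nucleotide fraction at or above which a mate
#'   is considered low-complexity and the pair rejected as an artefact
#'   (default 0.9).
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(barcode = "GCTATA", linker = "NNN",
                        r1_trim = 9L, r2_trim = 6L,
                        artefacts = NULL, rdna = NULL,
                        max_mismatch = 0L, low_complexity = 0.9) {
  r1_trim <- as.integer(r1_trim)
  r2_trim <- as.integer(r2_trim)
  if (r1_trim < 0L || r2_trim < 0L)
    stop("trim lengths must be non-negative")
  if (r1_trim < nchar(barcode))
    stop("r1_trim must be at least the barcode length")
  if (nchar(barcode) + nchar(linker) != r1_trim)
    stop("barcode + linker length must equal r1_trim (",
         nchar(barcode), " + ", nchar(linker), " != ", r1_trim, ")")
  if (is.character(artefacts) && length(artefacts) == 1L &&
      file.exists(artefacts) && !grepl("^[ACGTNacgtn]+$", artefacts))
    artefacts <- read_fasta_seqs(artefacts)
  if (is.character(rdna) && length(rdna) == 1L &&
      file.exists(rdna) && !grepl("^[ACGTNacgtn]+$", rdna))
    rdna <- read_fasta_seqs(rdna)
  structure(list(barcode = toupper(barcode), linker = toupper(linker),
                 r1_trim = r1_trim, r2_trim = r2_trim,
                 artefacts = artefacts, rdna = rdna,
                 max_mismatch = as.integer(max_mismatch),
                 low_complexity = low_complexity),
            class = "prep_config")
}

hamming_le <- function(a, b, k) {
  # a, b equal-length character scalars
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b)) <= k
}

linker_matches <- function(observed, pattern) {
  if (nchar(observed) != nchar(pattern)) return(FALSE)
  p <- strsplit(pattern, "")[[1]]
  o <- strsplit(observed, "")[[1]]
  all(p == "N" | p == o)
}

#' Demultiplex and trim raw read pairs
#'
#' Verifies that read1 begins with the sample barcode (within
#' `cfg$max_mismatch` mismatches) followed by the linker pattern, then trims
#' `r1_trim` bases from read1 and `r2_trim` bases from read2.  Pairs whose
#' read1 prefix does not match, or whose reads are shorter than the trim
#' lengths, are rejected as `Unextracted` (never truncated).
#'
#' @param pairs Pair table (see [read_fastq_pairs()]).
#' @param cfg A [prep_config()].
#' @return A list with elements `clean` (trimmed pair table) and
#'   `rejected` (data frame `read_id`, `stage`, `cause`).
#' @export
extract_and_trim <- function(pairs, cfg) {
  stopifnot(inherits(cfg, "prep_config"))
  bad_chr <- grepl("[^ACGTN]", toupper(pairs$seq1)) |
             grepl("[^ACGTN]", toupper(pairs$seq2))
  if (any(bad_chr))
    stop("non-IUPAC characters in reads: ",
         paste(utils::head(pairs$read_id[bad_chr], 3), collapse = ", "))
  n <- nrow(pairs)
  cause <- character(n)
  long_enough <- nchar(pairs$seq1) > cfg$r1_trim &
                 nchar(pairs$seq2) > cfg$r2_trim
  cause[!long_enough] <- "read too short to trim"
  bc_len <- nchar(cfg$barcode)
  ok <- long_enough
  if (any(ok)) {
    bc_obs <- substr(pairs$seq1[ok], 1L, bc_len)
    lk_obs <- substr(pairs$seq1[ok], bc_len + 1L, cfg$r1_trim)
    bc_ok <- vapply(bc_obs, hamming_le, logical(1),
                    b = cfg$barcode, k = cfg$max_mismatch)
    lk_ok <- vapply(lk_obs, linker_matches, logical(1),
                    pattern = cfg$linker)
    fail <- !(bc_ok & lk_ok)
    cause[which(ok)[fail]] <- "barcode/linker not found"
    ok[which(ok)[fail]] <- FALSE
  }
  clean <- pairs[ok, , drop = FALSE]
  if (nrow(clean)) {
    clean$seq1  <- substr(clean$seq1,  cfg$r1_trim + 1L, nchar(clean$seq1))
    clean$qual1 <- substr(clean$qual1, cfg$r1_trim + 1L, nchar(clean$qual1))
    clean$seq2  <- substr(clean$seq2,  cfg$r2_trim + 1L, nchar(clean$seq2))
    clean$qual2 <- substr(clean$qual2, cfg$r2_trim + 1L, nchar(clean$qual2))
  }
  rejected <- data.frame(read_id = pairs$read_id[!ok],
                         stage = rep("Unextracted", sum(!ok)),
                         cause = cause[!ok],
                         row.names = NULL, stringsAsFactors = FALSE)
  rownames(clean) <- NULL
  list(clean = clean, rejected = rejected)
}

# Does each query match any reference within k mismatches?  The shorter of
# query/reference is scanned over the longer at every offset (Biostrings).
match_any_ref <- function(queries, refs, k, both_strands = FALSE) {
  ref_sets <- Biostrings::DNAStringSet(unname(unlist(refs)))
  out <- logical(length(queries))
  for (i in seq_along(queries)) {
    q <- Biostrings::DNAString(queries[i])
    forms <- list(q)
    if (both_strands) forms <- c(forms, list(Biostrings::reverseComplement(q)))
    hit <- FALSE
    for (qq in forms) {
      for (j in seq_along(ref_sets)) {
        r <- ref_sets[[j]]
        if (length(qq) <= length(r)) {
          if (Biostrings::countPattern(qq, r, max.mismatch = k) > 0L) {
            hit <- TRUE; break
          }
        } else {
          if (Biostrings::countPattern(r, qq, max.mismatch = k) > 0L) {
            hit <- TRUE; break
          }
        }
      }
      if (hit) break
    }
    out[i] <- hit
  }
  out
}

mono_fraction <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  apply(f, 1L, max) / Biostrings::width(x)
}

#' Per-mate artefact filter
#'
#' A mate fails if it matches any artefact reference (forward strand,
#' within `cfg$max_mismatch`) or if its mono-nucleotide fraction reaches
#' `cfg$low_complexity`.
#'
#' @param pairs Trimmed pair table.
#' @param cfg A [prep_config()]; `artefacts` must be non-empty.
#' @return List of logicals `mate1`, `mate2` (TRUE = fails the filter).
#' @export
filter_artefacts <- function(pairs, cfg) {
  if (is.null(cfg$artefacts) || length(cfg$artefacts) == 0L)
    stop("artefact library is empty; configure prep_config(artefacts=)")
  verdict <- function(seqs) {
    if (!length(seqs)) return(logical(0))
    match_any_ref(seqs, cfg$artefacts, cfg$max_mismatch) |
      (mono_fraction(seqs) >= cfg$low_complexity)
  }
  list(mate1 = verdict(pairs$seq1), mate2 = verdict(pairs$seq2))
}

#' Per-mate ribosomal DNA filter
#'
#' A mate fails if it (or its reverse complement) matches the rDNA
#' reference within `cfg$max_mismatch` mismatches.
#'
#' @param pairs Trimmed pair table.
#' @param cfg A [prep_config()]; `rdna` must be set.
#' @return List of logicals `mate1`, `mate2` (TRUE = fails the filter).
#' @export
filter_rdna <- function(pairs, cfg) {
  if (is.null(cfg$rdna) || length(cfg$rdna) == 0L)
    stop("rDNA reference missing; configure prep_config(rdna=)")
  verdict <- function(seqs) {
    if (!length(seqs)) return(logical(0))
    match_any_ref(seqs, cfg$rdna, cfg$max_mismatch, both_strands = TRUE)
  }
  list(mate1 = verdict(pairs$seq1), mate2 = verdict(pairs$seq2))
}

#' Combine per-mate filter verdicts into a per-pair stage
#'
#' A pair survives only if both mates pass both filters.  A pair failing
#' both filters is counted once, at the earliest stage (Artefacts before
#' rDNA, matching the filter order).
#'
#' @param artefact Per-mate artefact verdicts ([filter_artefacts()]).
#' @param rdna Per-mate rDNA verdicts ([filter_rdna()]).
#' @return Character vector per pair: `"pass"`, `"Artefacts"` or `"rDNA"`.
#' @export
enforce_mate_consistency <- function(artefact, rdna) {
  n <- length(artefact$mate1)
  stopifnot(length(artefact$mate2) == n,
            length(rdna$mate1) == n, length(rdna$mate2) == n)
  out <- rep("pass", n)
  out[rdna$mate1 | rdna$mate2] <- "rDNA"
  out[artefact$mate1 | artefact$mate2] <- "Artefacts"
  out
}

#' Run the full read-preparation stage
#'
#' Demultiplexes and trims raw pairs, applies the artefact and rDNA
#' filters to both mates, removes pairs with any failing mate, and
#' returns the surviving clean pairs together with per-stage rejection
#' counts.  Conservation holds exactly:
#' `nrow(pairs) == nrow(clean) + Unextracted + Artefacts + rDNA`.
#'
#' @param pairs Raw pair table ([read_fastq_pairs()]).
#' @param cfg A [prep_config()].
#' @return List with `clean` (trimmed survivors), `rejections`
#'   (read_id/stage/cause), and `counts` (named integer vector
#'   Unextracted/Artefacts/rDNA).
#' @export
prep_reads <- function(pairs, cfg) {
  ext <- extract_and_trim(pairs, cfg)
  trimmed <- ext$clean
  art <- filter_artefacts(trimmed, cfg)
  rib <- filter_rdna(trimmed, cfg)
  stage <- enforce_mate_consistency(art, rib)
  keep <- stage == "pass"
  rej2 <- data.frame(read_id = trimmed$read_id[!keep],
                     stage = stage[!keep],
                     cause = ifelse(stage[!keep] == "Artefacts",
                                    "matched artefact library or low complexity",
                                    "matched rDNA reference"),
                     row.names = NULL, stringsAsFactors = FALSE)
  rejections <- rbind(ext$rejected, rej2)
  clean <- trimmed[keep, , drop = FALSE]
  rownames(clean) <- NULL
  counts <- c(Unextracted = nrow(ext$rejected),
              Artefacts = sum(stage == "Artefacts"),
              rDNA = sum(stage == "rDNA"))
  stopifnot(nrow(pairs) == nrow(clean) + sum(counts))
  list(clean = clean, rejections = rejections, counts = counts)
}
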