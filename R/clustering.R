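#' Remove PCR duplicates by coordinate identity
#'
#' Pairs with identical coordinates — same (chrom, strand, chromStart,
#' chromEnd) — are collapsed: of n such pairs, 1 is kept and n-1 are
#' counted as Duplicates.  Within a group the record with the highest
#' score (summed mapping quality) is kept; ties keep the
#' lexicographically smallest name.
#'
#' @param bed BED12 pair records from one library.
#' @return List with `kept` (BED12 data frame, input order preserved) and
#'   `n_duplicates` (integer).
#' @export
deduplicate_pairs <- function(bed) {
  if (nrow(bed) == 0L) return(list(kept = bed, n_duplicates = 0L))
  key <- paste(bed$chrom, bed$strand, bed$start, bed$end, sep = "\r")
  ord <- order(key, -bed$score, bed$name, method = "radix")
  first <- !duplicated(key[ord])
  keep_idx <- sort(ord[first])
  list(kept = `rownames<-`(bed[keep_idx, , drop = FALSE], NULL),
       n_duplicates = nrow(bed) - length(keep_idx))
}

#' Load and validate a seed peak set
#'
#' Seed peaks anchor clustering: the promoter-region intervals (e.g.
#' FANTOM5 DPI CAGE peaks) in which pair start sites are collected.
#' Same-strand seeds on a chromosome must not overlap; names must be
#' unique.  Violations are errors, never silently resolved.
#'
#' @param seeds BED6 data frame or a BED6 file path.
#' @return The validated seed data frame.
#' @export
load_seeds <- function(seeds) {
  if (is.character(seeds)) seeds <- read_bed6(seeds)
  if (anyDuplicated(seeds$name))
    stop("duplicate seed names: ",
         paste(utils::head(unique(seeds$name[duplicated(seeds$name)]), 3),
               collapse = ", "))
  if (any(seeds$start >= seeds$end))
    stop("seed intervals must satisfy start < end")
  gr <- seeds_granges(seeds)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits))
    stop("overlapping same-strand seeds: ",
         seeds$name[S4Vectors::queryHits(hits)[1]], " and ",
         seeds$name[S4Vectors::subjectHits(hits)[1]])
  seeds
}

seeds_granges <- function(seeds) {
  GenomicRanges::GRanges(
    seqnames = seeds$chrom,
    ranges = IRanges::IRanges(start = seeds$start + 1L, end = seeds$end),
    strand = ifelse(seeds$strand == ".", "*", seeds$strand))
}

#' Assign pair records to seed peaks by their TSS
#'
#' A record is assigned to the unique same-strand seed whose half-open
#' interval contains its TSS base (the record's thickStart); records whose
#' TSS misses every seed are unassigned (NA).
#'
#' @param bed BED12 pair records.
#' @param seeds Validated seed set ([load_seeds()]).
#' @return Character vector of seed names, NA where unassigned.
#' @export
assign_to_seed <- function(bed, seeds) {
  if (nrow(bed) == 0L) return(character(0))
  tss <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$thickStart + 1L, width = 1L),
    strand = bed$strand)
  hits <- GenomicRanges::findOverlaps(tss, seeds_granges(seeds))
  out <- rep(NA_character_, nrow(bed))
  out[S4Vectors::queryHits(hits)] <- seeds$name[S4Vectors::subjectHits(hits)]
  out
}

#' Assemble promoter-seeded CAGEscan clusters
#'
#' Groups deduplicated pair records by the seed containing their TSS and
#' merges each group into one BED12 transcript model: the blocks are the
#' interval union of all member blocks, the span covers the union, the
#' score is the member-pair count, and name/thickStart/thickEnd carry the
#' seed's identity and position.
#'
#' @param bed Deduplicated BED12 pair records from one library.
#' @param seeds Validated seed set ([load_seeds()]).
#' @return List with `clusters` (BED12 sorted by chrom, start) and
#'   `unassigned` (pair records whose TSS hit no seed).
#' @export
build_clusters <- function(bed, seeds) {
  seed_of <- assign_to_seed(bed, seeds)
  unassigned <- `rownames<-`(bed[is.na(seed_of), , drop = FALSE], NULL)
  assigned <- bed[!is.na(seed_of), , drop = FALSE]
  seed_of <- seed_of[!is.na(seed_of)]
  if (nrow(assigned) == 0L)
    return(list(clusters = empty_bed12(), unassigned = unassigned))
  rows <- lapply(split(seq_len(nrow(assigned)), seed_of), function(idx) {
    members <- assigned[idx, , drop = FALSE]
    ir <- IRanges::reduce(do.call(c, lapply(seq_len(nrow(members)),
      function(j) {
        sizes <- split_ints(members$blockSizes[j])[[1]]
        starts <- split_ints(members$blockStarts[j])[[1]]
        IRanges::IRanges(start = members$start[j] + starts + 1L,
                         width = sizes)
      })))
    s <- seeds[seeds$name == seed_of[idx[1]], , drop = FALSE]
    cs <- IRanges::start(ir)[1L] - 1L
    data.frame(
      chrom = members$chrom[1L], start = cs,
      end = IRanges::end(ir)[length(ir)],
      name = s$name, score = as.numeric(length(idx)), strand = s$strand,
      thickStart = s$start, thickEnd = s$end, itemRgb = "0",
      blockCount = length(ir),
      blockSizes = paste(IRanges::width(ir), collapse = ","),
      blockStarts = paste(IRanges::start(ir) - 1L - cs, collapse = ","),
      stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows)
  clusters <- clusters[order(clusters$chrom, clusters$start,
                             clusters$name, method = "radix"), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  list(clusters = clusters, unassigned = unassigned)
}

#' Merge per-library clusters into meta-clusters
#'
#' Clusters sharing a seed across libraries are merged: blocks are the
#' union across libraries and the score counts the distinct libraries
#' contributing at least one cluster for that seed (not the pair total).
#'
#' @param cluster_list Named list: library id -> BED12 cluster data frame.
#'   All entries must use the same seed universe; a seed name mapped to
#'   different thick coordinates across libraries is an error.
#' @return BED12 data frame of meta-clusters, sorted by (chrom, start).
#' @export
merge_meta <- function(cluster_list) {
  stopifnot(is.list(cluster_list), length(cluster_list) >= 1L,
            !is.null(names(cluster_list)))
  lib_ids <- names(cluster_list)
  all_rows <- do.call(rbind, lapply(unique(lib_ids), function(lib) {
    d <- cluster_list[[lib]]
    if (nrow(d)) d$library_id <- lib else d$library_id <- character(0)
    d
  }))
  if (is.null(all_rows) || nrow(all_rows) == 0L) return(empty_bed12())
  chk <- unique(all_rows[, c("name", "chrom", "strand",
                             "thickStart", "thickEnd")])
  if (anyDuplicated(chk$name))
    stop("seed name mapped to different coordinates across libraries: ",
         chk$name[duplicated(chk$name)][1])
  rows <- lapply(split(seq_len(nrow(all_rows)), all_rows$name),
    function(idx) {
      members <- all_rows[idx, , drop = FALSE]
      ir <- IRanges::reduce(do.call(c, lapply(seq_len(nrow(members)),
        function(j) {
          sizes <- split_ints(members$blockSizes[j])[[1]]
          starts <- split_ints(members$blockStarts[j])[[1]]
          IRanges::IRanges(start = members$start[j] + starts + 1L,
                           width = sizes)
        })))
      cs <- IRanges::start(ir)[1L] - 1L
      data.frame(
        chrom = members$chrom[1L], start = cs,
        end = IRanges::end(ir)[length(ir)],
        name = members$name[1L],
        score = as.numeric(length(unique(members$library_id))),
        strand = members$strand[1L],
        thickStart = members$thickStart[1L],
        thickEnd = members$thickEnd[1L], itemRgb = "0",
        blockCount = length(ir),
        blockSizes = paste(IRanges::width(ir), collapse = ","),
        blockStarts = paste(IRanges::start(ir) - 1L - cs, collapse = ","),
        stringsAsFactors = FALSE)
    })
  meta <- do.call(rbind, rows)
  meta <- meta[order(meta$chrom, meta$start, meta$name, method = "radix"), ,
               drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Derive de novo seeds from pair start sites
#'
#' When no external promoter peaks are supplied, the TSSs of the pairs
#' themselves are clustered by single linkage per (chrom, strand): TSS
#' positions at most `join_distance` bp apart join one seed, whose
#' interval spans [min TSS, max TSS + 1).  Names are generated as
#' `chrom:start..end,strand`.
#'
#' @param bed Deduplicated BED12 pair records.
#' @param join_distance Maximum gap (bp) joining neighbouring TSSs
#'   (default 20).
#' @return BED6 data frame of seeds (score 0).
#' @export
de_novo_seeds <- function(bed, join_distance = 20L) {
  if (join_distance < 0) stop("join_distance must be non-negative")
  if (nrow(bed) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  grp <- paste(bed$chrom, bed$strand, sep = "\r")
  rows <- lapply(split(bed$thickStart, grp), function(tss) {
    tss <- sort(unique(tss))
    brk <- cumsum(c(0L, diff(tss) > join_distance))
    t(vapply(split(tss, brk),
             function(g) c(min(g), max(g) + 1L), integer(2)))
  })
  keys <- rep(names(rows), vapply(rows, nrow, integer(1)))
  m <- do.call(rbind, rows)
  parts <- strsplit(keys, "\r")
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = m[, 1L], end = m[, 2L],
    name = NA_character_, score = 0,
    strand = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  out$name <- sprintf("%s:%d..%d,%s", out$chrom, out$start, out$end,
                      out$strand)
  out <- out[order(out$chrom, out$start, out$strand, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
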