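#' Configuration for a synthetic CAGEscan experiment
#'
#' Defines the study conditions emulated by the generator: a random
#' genome carrying spliced transcript models, each with a promoter seed
#' peak; paired 2x36 nt reads (read1 = barcode + linker + 5' cDNA,
#' read2 = 6 random-primer bases + a downstream transcript position);
#' and contaminant pairs injected at configured rates.
#'
#' @param seed RNG seed for the truth (genome/transcripts/seeds).
#' @param genome_length Length of the single genomic contig (bp).
#' @param n_transcripts Number of transcript models.
#' @param exons_per_transcript Integer range (min, max) of exon counts.
#' @param exon_length,intron_length Integer ranges (bp).
#' @param tss_peak_width Width (bp) of the promoter seed peak at each
#'   transcript 5' end; clean TSSs are drawn uniformly inside it.
#' @param pairs_per_transcript Integer range of read pairs per transcript.
#' @param r1_len,r2_len Raw read lengths (default 36/36).
#' @param r1_trim,r2_trim Prefix lengths removed at preparation
#'   (default 9/6); aligned portions are therefore 27 and 30 nt.
#' @param barcode Sample barcode placed on read1 (default "GCTATA").
#' @param duplicate_rate,artefact_rate,rdna_rate,improper_rate,unextracted_rate,nonaligned_rate
#'   Per-pair probabilities of each contamination class; the remainder
#'   are clean pairs.  Their sum must stay below 1.
#' @param per_base_error Substitution error rate applied to
#'   genome-derived read bases.
#' @param rdna_length Length of the synthetic rDNA contig.
#' @param mapq_values Discrete MAPQ values drawn per mate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L,
                       n_transcripts = 10L,
                       exons_per_transcript = c(1L, 3L),
                       exon_length = c(150L, 400L),
                       intron_length = c(100L, 800L),
                       tss_peak_width = 10L,
                       pairs_per_transcript = c(20L, 50L),
                       r1_len = 36L, r2_len = 36L,
                       r1_trim = 9L, r2_trim = 6L,
                       barcode = "GCTATA",
                       duplicate_rate = 0.1, artefact_rate = 0.02,
                       rdna_rate = 0.3, improper_rate = 0.05,
                       unextracted_rate = 0.1, nonaligned_rate = 0.02,
                       per_base_error = 0.01,
                       rdna_length = 2000L,
                       mapq_values = c(0L, 20L, 30L, 37L)) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_transcripts = as.integer(n_transcripts),
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              tss_peak_width = as.integer(tss_peak_width),
              pairs_per_transcript = as.integer(pairs_per_transcript),
              r1_len = as.integer(r1_len), r2_len = as.integer(r2_len),
              r1_trim = as.integer(r1_trim), r2_trim = as.integer(r2_trim),
              barcode = barcode,
              duplicate_rate = duplicate_rate,
              artefact_rate = artefact_rate, rdna_rate = rdna_rate,
              improper_rate = improper_rate,
              unextracted_rate = unextracted_rate,
              nonaligned_rate = nonaligned_rate,
              per_base_error = per_base_error,
              rdna_length = as.integer(rdna_length),
              mapq_values = as.integer(mapq_values))
  rates <- c(cfg$duplicate_rate, cfg$artefact_rate, cfg$rdna_rate,
             cfg$improper_rate, cfg$unextracted_rate, cfg$nonaligned_rate,
             cfg$per_base_error)
  if (any(rates < 0) || any(rates > 1))
    stop("rates must lie in [0, 1]")
  if (sum(rates[1:6]) >= 1)
    stop("contamination rates must sum to less than 1")
  la1 <- cfg$r1_len - cfg$r1_trim
  la2 <- cfg$r2_len - cfg$r2_trim
  if (la1 <= 0L || la2 <= 0L)
    stop("read lengths must exceed trim lengths")
  if (cfg$exon_length[1] < cfg$tss_peak_width + max(la1, la2))
    stop("minimum exon length must accommodate the seed peak plus a read")
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform draw from lo:hi that is safe for degenerate ranges (lo == hi)
sample_range <- function(lo, hi, n = 1L) {
  v <- lo:hi
  v[sample.int(length(v), n, replace = TRUE)]
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Fixed synthetic artefact library: stand-ins for empty-construct and
# primer sequences (labelled synthetic; not real oligo sequences).
#' Synthetic artefact reference library
#'
#' @return Named character vector of synthetic artefact sequences.
#' @export
synthetic_artefacts <- function() {
  c(synth_empty_construct = "ATCGCTAGCTAGGCTTAGCGCATGCTAGCATGCAAT",
    synth_primer = "GGTCACGTTCGAACGTGGTCACGTTCGAAC")
}

#' Generate the fixed truth of a synthetic experiment
#'
#' Draws the genome, a synthetic rDNA contig, and non-overlapping
#' transcript models with their promoter seed peaks.  Libraries simulated
#' from the same truth share seeds and differ only in read noise.
#'
#' @param cfg A [sim_config()]; `cfg$seed` fixes the truth.
#' @return List with `genome`, `rdna`, `artefacts` (named sequences),
#'   `transcripts` (data frame with comma-separated exon coordinates) and
#'   `seeds` (BED6 data frame).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- c(chr1 = random_dna(cfg$genome_length))
  rdna <- c(synthRDNA = random_dna(cfg$rdna_length))
  max_span <- cfg$exons_per_transcript[2] * cfg$exon_length[2] +
    (cfg$exons_per_transcript[2] - 1L) * cfg$intron_length[2]
  slot <- cfg$genome_length %/% cfg$n_transcripts
  if (slot < max_span + 10L)
    stop("genome_length too short for ", cfg$n_transcripts,
         " transcripts of maximum span ", max_span)
  tx <- vector("list", cfg$n_transcripts)
  seeds <- vector("list", cfg$n_transcripts)
  w <- cfg$tss_peak_width
  for (t in seq_len(cfg$n_transcripts)) {
    k <- sample_range(cfg$exons_per_transcript[1],
                      cfg$exons_per_transcript[2])
    ex_len <- sample_range(cfg$exon_length[1], cfg$exon_length[2], k)
    in_len <- if (k > 1L)
      sample_range(cfg$intron_length[1], cfg$intron_length[2], k - 1L)
    else integer(0)
    span <- sum(ex_len) + sum(in_len)
    offset <- sample.int(slot - span - 1L, 1L)
    start <- (t - 1L) * slot + offset
    es <- integer(k); ee <- integer(k)
    pos <- start
    for (j in seq_len(k)) {
      es[j] <- pos
      ee[j] <- pos + ex_len[j]
      pos <- ee[j] + if (j < k) in_len[j] else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      seed_start <- es[1]; seed_end <- es[1] + w
    } else {
      seed_start <- ee[k] - w; seed_end <- ee[k]
    }
    seed_name <- sprintf("peak_chr1_%d_%s", seed_start,
                         if (strand == "+") "p" else "m")
    tx[[t]] <- data.frame(
      tx_id = sprintf("tx%03d", t), chrom = "chr1",
      start = start, end = ee[k], strand = strand,
      exon_starts = paste(es, collapse = ","),
      exon_ends = paste(ee, collapse = ","),
      seed_name = seed_name, stringsAsFactors = FALSE)
    seeds[[t]] <- data.frame(
      chrom = "chr1", start = seed_start, end = seed_end,
      name = seed_name, score = 0, strand = strand,
      stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, tx)
  seeds <- do.call(rbind, seeds)
  seeds <- seeds[order(seeds$chrom, seeds$start, method = "radix"), ,
                 drop = FALSE]
  rownames(seeds) <- NULL
  list(genome = genome, rdna = rdna, artefacts = synthetic_artefacts(),
       transcripts = transcripts, seeds = seeds, cfg = cfg)
}

genome_sub <- function(genome, start0, len) {
  substr(genome, start0 + 1L, start0 + len)
}

inject_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  s <- strsplit(seq, "")[[1]]
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  }
  paste(s, collapse = "")
}

# draw one clean pair's alignment geometry for a transcript
draw_clean_pair <- function(txrow, cfg) {
  es <- as.integer(strsplit(txrow$exon_starts, ",")[[1]])
  ee <- as.integer(strsplit(txrow$exon_ends, ",")[[1]])
  k <- length(es)
  la1 <- cfg$r1_len - cfg$r1_trim
  la2 <- cfg$r2_len - cfg$r2_trim
  w <- cfg$tss_peak_width
  if (txrow$strand == "+") {
    tss <- es[1] + sample.int(w, 1L) - 1L
    j <- sample.int(k, 1L)
    p_min <- if (j == 1L) tss else es[j]
    p_max <- ee[j] - la2
    p <- p_min + sample.int(p_max - p_min + 1L, 1L) - 1L
    list(tss = tss,
         s1 = tss, e1 = tss + la1, strand1 = "+",
         s2 = p, e2 = p + la2, strand2 = "-")
  } else {
    tss <- ee[k] - sample.int(w, 1L)
    r1s <- tss - la1 + 1L
    j <- sample.int(k, 1L)
    p_min <- es[j]
    p_max <- if (j == k) min(r1s, tss + 1L - la2) else ee[j] - la2
    p <- p_min + sample.int(p_max - p_min + 1L, 1L) - 1L
    list(tss = tss,
         s1 = r1s, e1 = tss + 1L, strand1 = "-",
         s2 = p, e2 = p + la2, strand2 = "+")
  }
}

#' Simulate one CAGEscan library
#'
#' Emits raw paired reads (FASTQ-ready pair table), their genome
#' alignments (SAM record table, for pairs that survive preparation),
#' and per-pair ground-truth labels, from a fixed truth.  Clean pairs
#' have unique alignment coordinates; duplicate pairs are exact
#' coordinate copies of clean pairs.
#'
#' @param truth Output of [simulate_truth()].
#' @param library_id Library identifier used in read names.
#' @param read_seed RNG seed for the read-level noise (sampling,
#'   contamination, errors); defaults to the truth seed.
#' @param out_dir If non-NULL, write genome.fa, rdna.fa, artefacts.fa,
#'   r1.fq, r2.fq, aln.sam and truth/ files there.
#' @return List with `library_id`, `pairs` (raw FASTQ pair table), `sam`
#'   (SAM record table), `labels` (read_id/label/duplicate_of/
#'   transcript/seed_name), `truth`, and `files` (paths, if written).
#' @export
simulate_library <- function(truth, library_id = "lib1",
                             read_seed = truth$cfg$seed,
                             out_dir = NULL) {
  cfg <- truth$cfg
  set.seed(read_seed)
  genome <- truth$genome[["chr1"]]
  la1 <- cfg$r1_len - cfg$r1_trim
  la2 <- cfg$r2_len - cfg$r2_trim
  linker_len <- cfg$r1_trim - nchar(cfg$barcode)
  ntx <- nrow(truth$transcripts)
  n_per_tx <- sample_range(cfg$pairs_per_transcript[1],
                           cfg$pairs_per_transcript[2], ntx)
  n <- sum(n_per_tx)
  tx_of <- rep(seq_len(ntx), n_per_tx)
  probs <- c(unextracted = cfg$unextracted_rate,
             artefact = cfg$artefact_rate, rdna = cfg$rdna_rate,
             improper = cfg$improper_rate,
             nonaligned = cfg$nonaligned_rate,
             duplicate = cfg$duplicate_rate)
  u <- stats::runif(n)
  cuts <- cumsum(probs)
  label <- rep("clean", n)
  for (i in rev(seq_along(cuts)))
    label[u < cuts[i]] <- names(cuts)[i]
  # a duplicate must copy an already-drawn clean pair; promote any
  # duplicate drawn before the first clean pair
  first_clean <- match("clean", label)
  if (is.na(first_clean)) {
    label[label == "duplicate"] <- "clean"
    first_clean <- match("clean", label)
  }
  if (!is.na(first_clean) && first_clean > 1L)
    label[seq_len(first_clean - 1L)][
      label[seq_len(first_clean - 1L)] == "duplicate"] <- "clean"

  read_id <- sprintf("%s_read%06d", library_id, seq_len(n))
  seq1 <- character(n); seq2 <- character(n)
  sam_rows <- vector("list", n)
  dup_of <- rep(NA_character_, n)
  coord <- data.frame(tss = rep(NA_integer_, n),
                      s1 = NA_integer_, e1 = NA_integer_,
                      strand1 = NA_character_,
                      s2 = NA_integer_, e2 = NA_integer_,
                      strand2 = NA_character_, mapq1 = NA_integer_,
                      mapq2 = NA_integer_, stringsAsFactors = FALSE)
  used_keys <- new.env(hash = TRUE)
  clean_idx_so_far <- integer(0)

  r1_from_geom <- function(g) {
    core <- if (g$strand1 == "+")
      genome_sub(genome, g$s1, la1)
    else revcomp_chr(genome_sub(genome, g$s1, la1))
    paste0(cfg$barcode, random_dna(linker_len),
           inject_errors(core, cfg$per_base_error))
  }
  r2_from_geom <- function(g) {
    core <- if (g$strand2 == "+")
      genome_sub(genome, g$s2, la2)
    else revcomp_chr(genome_sub(genome, g$s2, la2))
    paste0(random_dna(cfg$r2_trim),
           inject_errors(core, cfg$per_base_error))
  }

  for (i in seq_len(n)) {
    lab <- label[i]
    if (lab == "clean") {
      txrow <- truth$transcripts[tx_of[i], , drop = FALSE]
      g <- NULL
      for (try in seq_len(100L)) {
        cand <- draw_clean_pair(txrow, cfg)
        key <- paste(cand$strand1, min(cand$s1, cand$s2),
                     max(cand$e1, cand$e2), sep = "_")
        if (!exists(key, envir = used_keys, inherits = FALSE)) {
          assign(key, TRUE, envir = used_keys)
          g <- cand
          break
        }
      }
      if (is.null(g))
        stop("could not draw a unique clean pair after 100 tries; ",
             "reduce pairs_per_transcript or widen the transcript models")
      clean_idx_so_far <- c(clean_idx_so_far, i)
    } else if (lab == "duplicate") {
      src <- clean_idx_so_far[sample.int(length(clean_idx_so_far), 1L)]
      dup_of[i] <- read_id[src]
      tx_of[i] <- tx_of[src]
      g <- as.list(coord[src, c("tss", "s1", "e1", "strand1",
                                "s2", "e2", "strand2")])
    } else if (lab == "improper") {
      mode <- sample(c("same_strand", "outward"), 1L)
      s1 <- sample.int(cfg$genome_length - la1, 1L) - 1L
      gap <- sample.int(500L, 1L)
      s2 <- min(s1 + la1 + gap, cfg$genome_length - la2 - 1L)
      if (mode == "same_strand") {
        g <- list(tss = NA_integer_, s1 = s1, e1 = s1 + la1,
                  strand1 = "+", s2 = s2, e2 = s2 + la2, strand2 = "+")
      } else {
        # minus-strand mate leftmost: outward-facing, fails FR
        g <- list(tss = NA_integer_, s1 = s1, e1 = s1 + la1,
                  strand1 = "-", s2 = s2, e2 = s2 + la2, strand2 = "+")
      }
    } else if (lab == "nonaligned") {
      which_unmapped <- sample(1:2, 1L)
      s <- sample.int(cfg$genome_length - max(la1, la2), 1L) - 1L
      if (which_unmapped == 1L) {
        g <- list(tss = NA_integer_, s1 = NA_integer_, e1 = NA_integer_,
                  strand1 = NA_character_, s2 = s, e2 = s + la2,
                  strand2 = "+")
      } else {
        g <- list(tss = NA_integer_, s1 = s, e1 = s + la1, strand1 = "+",
                  s2 = NA_integer_, e2 = NA_integer_,
                  strand2 = NA_character_)
      }
    } else {
      g <- list(tss = NA_integer_, s1 = NA_integer_, e1 = NA_integer_,
                strand1 = NA_character_, s2 = NA_integer_,
                e2 = NA_integer_, strand2 = NA_character_)
    }
    q1 <- cfg$mapq_values[sample.int(length(cfg$mapq_values), 1L)]
    q2 <- cfg$mapq_values[sample.int(length(cfg$mapq_values), 1L)]
    coord[i, ] <- list(g$tss, g$s1, g$e1, g$strand1, g$s2, g$e2,
                       g$strand2, q1, q2)

    # raw read sequences
    if (lab %in% c("clean", "duplicate")) {
      seq1[i] <- r1_from_geom(g)
      seq2[i] <- r2_from_geom(g)
    } else if (lab == "improper") {
      seq1[i] <- r1_from_geom(g)
      seq2[i] <- r2_from_geom(g)
    } else if (lab == "nonaligned") {
      if (is.na(g$s1)) {
        seq1[i] <- paste0(cfg$barcode, random_dna(linker_len),
                          random_dna(la1))
        seq2[i] <- r2_from_geom(g)
      } else {
        seq1[i] <- r1_from_geom(g)
        seq2[i] <- paste0(random_dna(cfg$r2_trim), random_dna(la2))
      }
    } else if (lab == "artefact") {
      art <- truth$artefacts[[sample.int(length(truth$artefacts), 1L)]]
      seq1[i] <- paste0(cfg$barcode, random_dna(linker_len),
                        random_dna(la1))
      seq2[i] <- paste0(random_dna(cfg$r2_trim), substr(art, 1L, la2))
    } else if (lab == "rdna") {
      rd <- truth$rdna[[1]]
      p1 <- sample.int(nchar(rd) - la1, 1L) - 1L
      p2 <- sample.int(nchar(rd) - la2, 1L) - 1L
      part1 <- genome_sub(rd, p1, la1)
      part2 <- genome_sub(rd, p2, la2)
      if (stats::runif(1) < 0.5) part1 <- revcomp_chr(part1)
      if (stats::runif(1) < 0.5) part2 <- revcomp_chr(part2)
      seq1[i] <- paste0(cfg$barcode, random_dna(linker_len), part1)
      seq2[i] <- paste0(random_dna(cfg$r2_trim), part2)
    } else if (lab == "unextracted") {
      prefix <- random_dna(cfg$r1_trim)
      while (substr(prefix, 1L, nchar(cfg$barcode)) == cfg$barcode)
        prefix <- random_dna(cfg$r1_trim)
      seq1[i] <- paste0(prefix, random_dna(la1))
      seq2[i] <- paste0(random_dna(cfg$r2_trim), random_dna(la2))
    }

    # SAM records for pairs that survive preparation
    if (lab %in% c("clean", "duplicate", "improper", "nonaligned")) {
      sam_rows[[i]] <- sam_records_for(g, read_id[i], q1, q2,
                                       lab %in% c("clean", "duplicate"),
                                       genome, la1, la2)
    }
  }

  labels <- data.frame(read_id = read_id, label = label,
                       duplicate_of = dup_of,
                       transcript = ifelse(
                         label %in% c("clean", "duplicate"),
                         truth$transcripts$tx_id[tx_of], NA_character_),
                       seed_name = ifelse(
                         label %in% c("clean", "duplicate"),
                         truth$transcripts$seed_name[tx_of], NA_character_),
                       stringsAsFactors = FALSE)
  coord$mapq1 <- as.integer(coord$mapq1)
  coord$mapq2 <- as.integer(coord$mapq2)
  for (cc in c("tss", "s1", "e1", "s2", "e2"))
    coord[[cc]] <- as.integer(coord[[cc]])
  qual_for <- function(s) strrep("I", nchar(s))
  pairs <- data.frame(read_id = read_id, seq1 = seq1,
                      qual1 = qual_for(seq1), seq2 = seq2,
                      qual2 = qual_for(seq2), stringsAsFactors = FALSE)
  sam <- do.call(rbind, sam_rows[!vapply(sam_rows, is.null, logical(1))])
  rownames(sam) <- NULL
  sim <- list(library_id = library_id, pairs = pairs, sam = sam,
              labels = labels, coord = coord, truth = truth)
  if (!is.null(out_dir)) sim$files <- write_simulation(sim, out_dir)
  sim
}

# SAM rows (one per mate) for a pair geometry; 0-based coords in g.
sam_records_for <- function(g, qname, q1, q2, proper, genome, la1, la2) {
  m1_mapped <- !is.na(g$s1)
  m2_mapped <- !is.na(g$s2)
  f1 <- 0x1L + 0x40L
  f2 <- 0x1L + 0x80L
  if (proper) { f1 <- f1 + 0x2L; f2 <- f2 + 0x2L }
  if (!m1_mapped) { f1 <- f1 + 0x4L; f2 <- f2 + 0x8L }
  if (!m2_mapped) { f2 <- f2 + 0x4L; f1 <- f1 + 0x8L }
  if (m1_mapped && g$strand1 == "-") { f1 <- f1 + 0x10L; f2 <- f2 + 0x20L }
  if (m2_mapped && g$strand2 == "-") { f2 <- f2 + 0x10L; f1 <- f1 + 0x20L }
  span <- if (m1_mapped && m2_mapped)
    max(g$e1, g$e2) - min(g$s1, g$s2) else 0L
  tlen1 <- 0L; tlen2 <- 0L
  if (m1_mapped && m2_mapped) {
    if (g$s1 <= g$s2) { tlen1 <- span; tlen2 <- -span }
    else { tlen1 <- -span; tlen2 <- span }
  }
  row <- function(flag, s, len, mq, mate_s, tlen, seq) {
    data.frame(qname = qname, flag = flag,
               rname = if (is.na(s)) "*" else "chr1",
               pos = if (is.na(s)) 0L else s + 1L,
               mapq = if (is.na(s)) 0L else mq,
               cigar = if (is.na(s)) "*" else paste0(len, "M"),
               rnext = if (is.na(mate_s)) "*" else "=",
               pnext = if (is.na(mate_s)) 0L else mate_s + 1L,
               tlen = tlen, seq = seq, qual = strrep("I", nchar(seq)),
               stringsAsFactors = FALSE)
  }
  seq1 <- if (m1_mapped) genome_sub(genome, g$s1, la1) else strrep("N", la1)
  seq2 <- if (m2_mapped) genome_sub(genome, g$s2, la2) else strrep("N", la2)
  rbind(row(f1, g$s1, la1, q1, g$s2, tlen1, seq1),
        row(f2, g$s2, la2, q2, g$s1, tlen2, seq2))
}

#' Write SAM records to a text SAM file
#'
#' @param sam SAM record table (qname/flag/rname/pos/mapq/cigar/rnext/
#'   pnext/tlen/seq/qual).
#' @param sq Named integer vector of reference lengths for the header.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sam <- function(sam, sq, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- if (is.null(sam) || nrow(sam) == 0L) character(0) else
    do.call(paste, c(sam[, c("qname", "flag", "rname", "pos", "mapq",
                             "cigar", "rnext", "pnext", "tlen", "seq",
                             "qual")], sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read raw SAM records back into a record table
#'
#' Inverse of [write_sam()] (record fields 1-11, tags dropped); used for
#' round-trip checks.  Semantic pairing for the pipeline goes through
#' [read_pairs_from_sam()] instead.
#'
#' @param path SAM file.
#' @return SAM record table as in [write_sam()].
#' @export
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[`, character(1), i)
  data.frame(qname = get(1), flag = as.integer(get(2)), rname = get(3),
             pos = as.integer(get(4)), mapq = as.integer(get(5)),
             cigar = get(6), rnext = get(7), pnext = as.integer(get(8)),
             tlen = as.integer(get(9)), seq = get(10), qual = get(11),
             stringsAsFactors = FALSE)
}

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  truth <- sim$truth
  files <- list(
    genome = file.path(out_dir, "genome.fa"),
    rdna = file.path(out_dir, "rdna.fa"),
    artefacts = file.path(out_dir, "artefacts.fa"),
    r1 = file.path(out_dir, "r1.fq"),
    r2 = file.path(out_dir, "r2.fq"),
    sam = file.path(out_dir, "aln.sam"),
    seeds = file.path(out_dir, "truth", "seeds.bed"),
    labels = file.path(out_dir, "truth", "labels.tsv"),
    clusters = file.path(out_dir, "truth", "clusters.bed12"),
    transcripts = file.path(out_dir, "truth", "transcripts.bed12"))
  write_fasta_seqs(truth$genome, files$genome)
  write_fasta_seqs(truth$rdna, files$rdna)
  write_fasta_seqs(truth$artefacts, files$artefacts)
  write_fastq_pairs(sim$pairs, files$r1, files$r2)
  write_sam(sim$sam, c(chr1 = truth$cfg$genome_length), files$sam)
  write_bed6(truth$seeds, files$seeds)
  utils::write.table(sim$labels, files$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed12(truth_clusters(sim), files$clusters, strict_bed = FALSE)
  write_bed12(transcript_models_bed12(truth), files$transcripts,
              strict_bed = FALSE)
  files
}

transcript_models_bed12 <- function(truth) {
  tx <- truth$transcripts
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    es <- as.integer(strsplit(tx$exon_starts[i], ",")[[1]])
    ee <- as.integer(strsplit(tx$exon_ends[i], ",")[[1]])
    data.frame(chrom = tx$chrom[i], start = tx$start[i], end = tx$end[i],
               name = tx$tx_id[i], score = 0, strand = tx$strand[i],
               thickStart = tx$start[i], thickEnd = tx$end[i],
               itemRgb = "0", blockCount = length(es),
               blockSizes = paste(ee - es, collapse = ","),
               blockStarts = paste(es - tx$start[i], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expected clusters from simulation ground truth
#'
#' An independent, deliberately simple reference: the clean,
#' non-duplicate pairs are grouped by their transcript's seed and their
#' mate intervals are unioned on a per-base bitmap.  The pipeline's
#' clusters must equal this field for field.
#'
#' @param sim Output of [simulate_library()].
#' @return BED12 data frame sorted by (chrom, start).
#' @export
truth_clusters <- function(sim) {
  keep <- sim$labels$label == "clean"
  if (!any(keep)) return(empty_bed12())
  seeds <- sim$truth$seeds
  seed_of <- sim$labels$seed_name[keep]
  co <- sim$coord[keep, , drop = FALSE]
  rows <- lapply(split(seq_len(nrow(co)), seed_of), function(idx) {
    lo <- min(co$s1[idx], co$s2[idx])
    hi <- max(co$e1[idx], co$e2[idx])
    bitmap <- logical(hi - lo)
    for (i in idx) {
      bitmap[(co$s1[i] - lo + 1L):(co$e1[i] - lo)] <- TRUE
      bitmap[(co$s2[i] - lo + 1L):(co$e2[i] - lo)] <- TRUE
    }
    r <- rle(bitmap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based within bitmap
    bs <- starts[r$values] + lo
    be <- ends[r$values] + lo
    s <- seeds[seeds$name == seed_of[idx[1]], , drop = FALSE]
    data.frame(chrom = "chr1", start = bs[1], end = be[length(be)],
               name = s$name, score = as.numeric(length(idx)), strand = s$strand,
               thickStart = s$start, thickEnd = s$end, itemRgb = "0",
               blockCount = length(bs),
               blockSizes = paste(be - bs, collapse = ","),
               blockStarts = paste(bs - bs[1], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$name, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
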