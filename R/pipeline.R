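#' Run the CAGEscan processing pipeline for one library
#'
#' Chains the stages deterministically: read preparation (demultiplex,
#' trim, artefact/rDNA filtering), alignment pair classification,
#' BED12 conversion, deduplication, and promoter-seeded clustering;
#' optionally start-site annotation.  Per-stage outputs, the QC triples
#' ledger and a JSON run manifest (inputs, outputs, checksums, config
#' snapshot) are written under `out_dir`.
#'
#' @param library_id Library identifier (ledger subject).
#' @param r1,r2 Raw FASTQ paths (read1 = CAGE, read2 = CAGEscan).
#' @param sam SAM/BAM alignments of the cleaned pairs.
#' @param out_dir Output directory (created if needed).
#' @param seeds BED6 seed-peak file or data frame; NULL derives de novo
#'   seeds from the pairs' own TSSs.
#' @param artefacts,rdna FASTA paths or named sequence vectors for the
#'   preparation filters.
#' @param prep A [prep_config()]; built from `artefacts`/`rdna` when NULL.
#' @param policy A [proper_pair_policy()].
#' @param join_distance De novo seed join distance (bp), used when
#'   `seeds` is NULL.
#' @param promoters,exons Optional BED6 annotation files or data frames;
#'   when both given, start-site classes are computed.
#' @param strict_bed Clamp BED scores to 0..1000 on output.
#' @return List with `ledger` (a [qc_ledger()]), `clusters`,
#'   `unassigned`, `pairs_bed` (deduplicated pair records), `seeds`,
#'   `annotation` (factor or NULL) and `manifest` (path).
#' @export
run_pipeline <- function(library_id, r1, r2, sam, out_dir,
                         seeds = NULL, artefacts = NULL, rdna = NULL,
                         prep = NULL, policy = proper_pair_policy(),
                         join_distance = 20L,
                         promoters = NULL, exons = NULL,
                         strict_bed = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prep))
    prep <- prep_config(artefacts = artefacts, rdna = rdna)

  raw <- read_fastq_pairs(r1, r2)
  prepped <- prep_reads(raw, prep)
  clean_fq1 <- file.path(out_dir, "clean.r1.fq")
  clean_fq2 <- file.path(out_dir, "clean.r2.fq")
  write_fastq_pairs(prepped$clean, clean_fq1, clean_fq2)

  aln <- read_pairs_from_sam(sam)
  aln <- aln[aln$read_id %in% prepped$clean$read_id, , drop = FALSE]
  cls <- classify_pair(aln, policy)
  proper <- aln[cls == "Proper", , drop = FALSE]

  pairs_bed <- pair_to_bed12(proper, policy)
  dedup <- deduplicate_pairs(pairs_bed)
  pairs_path <- file.path(out_dir, "pairs.bed12")
  write_bed12(dedup$kept, pairs_path, strict_bed = strict_bed)

  if (is.null(seeds)) {
    seeds <- de_novo_seeds(dedup$kept, join_distance)
  } else {
    seeds <- load_seeds(seeds)
  }
  built <- build_clusters(dedup$kept, seeds)
  clusters_path <- file.path(out_dir, "clusters.bed12")
  unassigned_path <- file.path(out_dir, "unassigned.bed12")
  write_bed12(built$clusters, clusters_path, strict_bed = strict_bed)
  write_bed12(built$unassigned, unassigned_path, strict_bed = strict_bed)

  ledger <- qc_ledger(
    library_id,
    unextracted = prepped$counts[["Unextracted"]],
    artefacts = prepped$counts[["Artefacts"]],
    rdna = prepped$counts[["rDNA"]],
    non_aligned = sum(cls == "NonAligned"),
    non_proper = sum(cls == "NonProper"),
    duplicates = dedup$n_duplicates,
    cagescan_pairs = nrow(dedup$kept),
    total = nrow(raw))
  ledger_path <- file.path(out_dir, "qc.tsv")
  write_ledger(ledger, ledger_path)

  annotation <- NULL
  if (!is.null(promoters) && !is.null(exons)) {
    if (is.character(promoters)) promoters <- read_bed6(promoters)
    if (is.character(exons)) exons <- read_bed6(exons)
    annotation <- classify_start(dedup$kept, promoters, exons)
  }

  outputs <- c(clean_fq1, clean_fq2, pairs_path, clusters_path,
               unassigned_path, ledger_path)
  manifest <- list(
    library_id = library_id,
    tool = paste("cagescanr",
                 as.character(utils::packageVersion("cagescanr"))),
    inputs = file_manifest(c(r1 = r1, r2 = r2, sam = sam)),
    outputs = file_manifest(stats::setNames(outputs, basename(outputs))),
    config = list(barcode = prep$barcode, linker = prep$linker,
                  r1_trim = prep$r1_trim, r2_trim = prep$r2_trim,
                  max_mismatch = prep$max_mismatch,
                  low_complexity = prep$low_complexity,
                  max_span = policy$max_span,
                  require_head_to_head = policy$require_head_to_head,
                  join_distance = join_distance,
                  strict_bed = strict_bed),
    ledger = as.list(ledger$counts))
  validate_ledger(ledger)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  list(ledger = ledger, clusters = built$clusters,
       unassigned = built$unassigned, pairs_bed = dedup$kept,
       seeds = seeds, annotation = annotation, manifest = manifest_path)
}

file_manifest <- function(paths) {
  lapply(as.list(paths), function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
}
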