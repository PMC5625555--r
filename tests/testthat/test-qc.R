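test_that("ledger triples are written in fixed order and re-read intact", {
  led <- qc_ledger("libX", unextracted = 10L, artefacts = 5L, rdna = 20L,
                   non_aligned = 5L, non_proper = 10L, duplicates = 20L,
                   cagescan_pairs = 30L)
  expect_equal(led$counts[["Total"]], 100L)
  path <- tempfile(fileext = ".tsv")
  write_ledger(led, path)
  lines <- readLines(path)
  expect_length(lines, 8L)
  expect_equal(lines[1], "libX\tTotal\t100")
  expect_equal(lines[8], "libX\tCAGEscanPairs\t30")
  back <- read_ledger(path)
  expect_equal(back[["libX"]]$counts, led$counts)
  # all-zero ledger is valid
  z <- qc_ledger("zero")
  write_ledger(z, path)
  expect_length(readLines(path), 8L)
})

test_that("a ledger violating the partition is refused", {
  expect_error(qc_ledger("bad", unextracted = 1L, total = 5L), "partition")
  led <- qc_ledger("libX", cagescan_pairs = 3L)
  led$counts[["Total"]] <- 99L
  expect_error(write_ledger(led, tempfile()), "partition")
})

test_that("start-site classes follow Promoter > Exon > Other precedence", {
  prom <- seed_row(name = "p1", start = 90L, end = 110L)
  exon <- seed_row(name = "e1", start = 100L, end = 300L)
  both <- classify_start(bed12_row(tss = 105L), prom, exon)
  expect_equal(as.character(both), "Promoter")
  only_exon <- classify_start(bed12_row(tss = 200L), prom, exon)
  expect_equal(as.character(only_exon), "Exon")
  neither <- classify_start(bed12_row(tss = 500L), prom, exon)
  expect_equal(as.character(neither), "Other")
  # unstranded annotation matches both strands
  prom_un <- seed_row(name = "p1", start = 90L, end = 110L, strand = ".")
  minus <- classify_start(bed12_row(tss = 100L, strand = "-"), prom_un,
                          exon[0, ])
  expect_equal(as.character(minus), "Promoter")
  # stranded promoter does not match the opposite strand
  minus2 <- classify_start(bed12_row(tss = 100L, strand = "-"), prom,
                           exon[0, ])
  expect_equal(as.character(minus2), "Other")
})

test_that("classification matches a per-base bitmap oracle on random input", {
  set.seed(17)
  L <- 2000L
  mk_ann <- function(n, stranded) do.call(rbind, lapply(seq_len(n),
    function(i) {
      s <- sample.int(L - 50L, 1) - 1L
      seed_row(name = paste0("a", i), start = s, end = s + sample.int(40L, 1),
               strand = if (stranded) sample(c("+", "-"), 1) else ".")
    }))
  prom <- mk_ann(15L, TRUE)
  exon <- mk_ann(25L, FALSE)
  n <- 1000L
  tss <- sample.int(L, n) - 1L
  st <- sample(c("+", "-"), n, replace = TRUE)
  bed <- do.call(rbind, lapply(seq_len(n), function(i)
    bed12_row(name = paste0("r", i), start = tss[i], end = tss[i] + 30L,
              tss = tss[i], strand = st[i])))
  got <- classify_start(bed, prom, exon)
  member <- function(ann, pos, strand) {
    any(ann$start <= pos & pos < ann$end &
          (ann$strand == "." | ann$strand == strand))
  }
  oracle <- vapply(seq_len(n), function(i) {
    if (member(prom, tss[i], st[i])) "Promoter"
    else if (member(exon, tss[i], st[i])) "Exon"
    else "Other"
  }, character(1))
  expect_equal(as.character(got), oracle)
  frac <- table(got) / n
  expect_equal(sum(frac), 1)
})

test_that("peak detection thresholds on cluster score", {
  cl <- rbind(bed12_row(name = "p1", score = 1),
              bed12_row(name = "p2", start = 600L, end = 700L, tss = 600L,
                        score = 3),
              bed12_row(name = "p3", start = 800L, end = 900L, tss = 800L,
                        score = 7))
  expect_setequal(detected_peaks(cl), c("p1", "p2", "p3"))
  expect_setequal(detected_peaks(cl, min_pairs = 2L), c("p2", "p3"))
  expect_length(detected_peaks(cl[0, ]), 0L)
})

test_that("Jaccard matrix matches set arithmetic and is well-formed", {
  sets <- list(A = c("p1", "p2", "p3"), B = c("p2", "p3", "p4"),
               C = character(0), D = c("p1", "p2", "p3"))
  m <- jaccard_matrix(sets)
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["A", "D"], 1.0)
  expect_equal(m["A", "C"], 0.0)
  expect_equal(m["C", "C"], 0.0)      # both-empty convention
  expect_equal(m["A", "A"], 1.0)
  expect_true(isSymmetric(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(jaccard_matrix(sets["A"]), "two libraries")
})

test_that("best_match finds the replicate and breaks ties lexicographically", {
  sets <- list(A = c("p1", "p2", "p3"), B = c("p2", "p3", "p4"),
               Z = c("p1", "p2", "p3"))
  m <- jaccard_matrix(sets)
  expect_equal(best_match(m, "A"), "Z")
  expect_equal(best_match(m, "Z"), "A")
  # all-equal row: lexicographically first other library
  m2 <- jaccard_matrix(list(A = "p1", B = "p2", C = "p3"))
  expect_equal(best_match(m2, "B"), "A")
  expect_error(best_match(m["A", "A", drop = FALSE], "A"), "single")
})
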