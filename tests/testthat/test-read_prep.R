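cfg0 <- function(...) {
  prep_config(artefacts = synthetic_artefacts(),
              rdna = c(synthRDNA = paste(rep("ACGTTGCA", 40), collapse = "")),
              ...)
}

test_that("extract_and_trim removes barcode+linker prefix and primer bases", {
  body1 <- "ACGTACGTACGTACGTACGTACGTACG"       # 27 nt
  p <- raw_pair(seq1 = paste0("GCTATA", "TTG", body1),
                seq2 = strrep("ACGT", 9))      # 36 nt
  res <- extract_and_trim(p, cfg0())
  expect_equal(nrow(res$clean), 1L)
  expect_equal(res$clean$seq1, body1)
  expect_equal(nchar(res$clean$seq1), 27L)
  expect_equal(nchar(res$clean$seq2), 30L)
  expect_equal(nchar(res$clean$qual1), 27L)
})

test_that("pairs without the barcode, and too-short reads, are Unextracted", {
  p <- rbind(raw_pair("no_bc", seq1 = strrep("T", 36), seq2 = strrep("A", 36)),
             raw_pair("short", seq1 = "GCTATAA", seq2 = strrep("A", 36)))
  res <- extract_and_trim(p, cfg0())
  expect_equal(nrow(res$clean), 0L)
  expect_equal(res$rejected$stage, c("Unextracted", "Unextracted"))
  # rejection, never truncation
  expect_false("short" %in% res$clean$read_id)
})

test_that("a zero-trim configuration is the identity on clean reads", {
  cfg <- prep_config(barcode = "", linker = "", r1_trim = 0L, r2_trim = 0L,
                     artefacts = synthetic_artefacts(),
                     rdna = c(r = strrep("ACGTTGCA", 40)))
  p <- raw_pair(seq1 = "ACGTACGTACGT", seq2 = "TTGACCATGGCA")
  res <- extract_and_trim(p, cfg)
  expect_identical(res$clean, p)
})

test_that("non-IUPAC characters are an input error, not a rejection", {
  p <- raw_pair(seq1 = paste0("GCTATA", "TTG", strrep("Z", 27)),
                seq2 = strrep("A", 36))
  expect_error(extract_and_trim(p, cfg0()), "non-IUPAC")
})

test_that("artefact filter rejects matching and low-complexity mates", {
  art <- synthetic_artefacts()
  cfg <- cfg0()
  p <- rbind(
    raw_pair("hit",  seq1 = strrep("ACTG", 7),
             seq2 = substr(art[["synth_primer"]], 1, 30)),
    raw_pair("rand", seq1 = "ACGGTCAGGTACCATGGTACCGATGCT",
             seq2 = "TGACCATGGTACCAGGTTACGGATCCAGTT"),
    raw_pair("mono", seq1 = strrep("A", 27),
             seq2 = "TGACCATGGTACCAGGTTACGGATCCAGTT"))
  v <- filter_artefacts(p, cfg)
  expect_equal(v$mate2, c(TRUE, FALSE, FALSE))
  expect_equal(v$mate1, c(FALSE, FALSE, TRUE))  # mono-A fraction 1.0 >= 0.9
  expect_error(filter_artefacts(p, prep_config(rdna = "ACGT")),
               "artefact library")
})

test_that("rDNA filter matches both strands; verdicts agree with a brute-force scan", {
  set.seed(11)
  rdna <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  cfg <- prep_config(artefacts = synthetic_artefacts(),
                     rdna = c(synthRDNA = rdna))
  sub30 <- substr(rdna, 51, 80)
  rc30 <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(sub30, "")[[1]]), collapse = ""))
  rand <- replicate(10, paste(sample(c("A", "C", "G", "T"), 30,
                                     replace = TRUE), collapse = ""))
  p <- do.call(rbind, c(
    list(raw_pair("fwd", seq1 = rand[1], seq2 = sub30),
         raw_pair("rev", seq1 = rand[2], seq2 = rc30)),
    lapply(3:10, function(i) raw_pair(paste0("r", i), seq1 = rand[i - 1],
                                      seq2 = rand[i]))))
  v <- filter_rdna(p, cfg)
  oracle <- vapply(p$seq2, brute_match, logical(1), r = rdna, k = 0,
                   both_strands = TRUE)
  expect_equal(unname(v$mate2), unname(oracle))
  expect_true(v$mate2[1] && v$mate2[2])
  # 1-mismatch policy, checked against the brute-force Hamming oracle
  cfg1 <- prep_config(artefacts = synthetic_artefacts(),
                      rdna = c(synthRDNA = rdna), max_mismatch = 1L)
  v1 <- filter_rdna(p, cfg1)
  oracle1 <- vapply(p$seq2, brute_match, logical(1), r = rdna, k = 1,
                    both_strands = TRUE)
  expect_equal(unname(v1$mate2), unname(oracle1))
})

test_that("a pair failing both filters is counted once, at the Artefacts stage", {
  art <- list(mate1 = c(FALSE, FALSE, FALSE), mate2 = c(TRUE, FALSE, TRUE))
  rib <- list(mate1 = c(FALSE, FALSE, TRUE), mate2 = c(FALSE, FALSE, FALSE))
  stage <- enforce_mate_consistency(art, rib)
  expect_equal(stage, c("Artefacts", "pass", "Artefacts"))
})

test_that("prep stage conserves pairs exactly across categories", {
  set.seed(3)
  for (rep in 1:5) {
    cfg <- small_sim_config(seed = rep * 7L,
                            unextracted_rate = stats::runif(1, 0, 0.3),
                            rdna_rate = stats::runif(1, 0, 0.3),
                            artefact_rate = stats::runif(1, 0, 0.2))
    truth <- simulate_truth(cfg)
    sim <- simulate_library(truth, "lib", read_seed = rep)
    pc <- prep_config(artefacts = truth$artefacts, rdna = truth$rdna)
    res <- prep_reads(sim$pairs, pc)
    expect_equal(nrow(sim$pairs), nrow(res$clean) + sum(res$counts))
    # each rejected pair appears exactly once
    expect_equal(anyDuplicated(res$rejections$read_id), 0L)
    expect_length(intersect(res$clean$read_id, res$rejections$read_id), 0L)
  }
})
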