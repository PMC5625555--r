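test_that("n identical-coordinate pairs keep 1 and count n-1 duplicates", {
  for (n in c(1L, 3L, 7L)) {
    bed <- do.call(rbind, lapply(seq_len(n), function(i)
      bed12_row(name = paste0("r", i), score = 10 * i)))
    res <- deduplicate_pairs(bed)
    expect_equal(nrow(res$kept), 1L)
    expect_equal(res$n_duplicates, n - 1L)
    expect_equal(res$kept$name, paste0("r", n))   # highest score wins
  }
  empty <- deduplicate_pairs(bed12_row()[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(empty$n_duplicates, 0L)
})

test_that("duplicate groups break score ties to the smallest name", {
  k1 <- rbind(bed12_row(name = "a", score = 40),
              bed12_row(name = "b", score = 50),
              bed12_row(name = "c", score = 50))
  k2 <- rbind(bed12_row(name = "d", start = 900L, end = 960L, tss = 900L,
                        score = 10),
              bed12_row(name = "e", start = 900L, end = 960L, tss = 900L,
                        score = 20))
  res <- deduplicate_pairs(rbind(k1, k2))
  expect_equal(res$n_duplicates, 3L)
  expect_setequal(res$kept$name, c("b", "e"))
})

test_that("records on the same span but opposite strands are not duplicates", {
  bed <- rbind(bed12_row(name = "f", strand = "+"),
               bed12_row(name = "r", strand = "-", tss = 529L))
  expect_equal(deduplicate_pairs(bed)$n_duplicates, 0L)
})

test_that("seed loading rejects same-strand overlaps and duplicate names", {
  ok <- rbind(seed_row(name = "s1", start = 95L, end = 105L),
              seed_row(name = "s2", start = 105L, end = 115L),
              seed_row(name = "s3", start = 95L, end = 105L, strand = "-"))
  expect_silent(load_seeds(ok))
  bad <- rbind(seed_row(name = "s1", start = 95L, end = 105L),
               seed_row(name = "s2", start = 100L, end = 110L))
  expect_error(load_seeds(bad), "overlap")
  dup <- rbind(seed_row(name = "s1"), seed_row(name = "s1", start = 300L,
                                               end = 310L))
  expect_error(load_seeds(dup), "duplicate")
})

test_that("TSS-to-seed assignment is strand-aware with half-open edges", {
  seeds <- load_seeds(rbind(seed_row(name = "s1", start = 95L, end = 105L)))
  expect_equal(assign_to_seed(bed12_row(tss = 100L), seeds), "s1")
  expect_equal(assign_to_seed(bed12_row(tss = 95L), seeds), "s1")
  expect_true(is.na(assign_to_seed(bed12_row(tss = 105L), seeds)))
  expect_true(is.na(assign_to_seed(bed12_row(tss = 100L, strand = "-"),
                                   seeds)))
  # brute-force scan over all seeds agrees
  set.seed(5)
  seeds2 <- load_seeds(do.call(rbind, lapply(0:9, function(i)
    seed_row(name = paste0("p", i), start = i * 50L, end = i * 50L + 20L,
             strand = if (i %% 2) "+" else "-"))))
  for (i in 1:50) {
    tss <- sample.int(520L, 1) - 1L
    st <- sample(c("+", "-"), 1)
    got <- assign_to_seed(bed12_row(tss = tss, start = tss,
                                    end = tss + 30L, strand = st), seeds2)
    want <- seeds2$name[seeds2$strand == st & seeds2$start <= tss &
                          tss < seeds2$end]
    if (length(want) == 0) expect_true(is.na(got)) else
      expect_equal(got, want)
  }
})

test_that("clusters union member blocks and count members in the score", {
  seeds <- load_seeds(seed_row(name = "s1", start = 95L, end = 105L))
  a <- bed12_row(name = "A", start = 100L, end = 530L, tss = 100L,
                 blockSizes = "36,30", blockStarts = "0,400")
  b <- bed12_row(name = "B", start = 98L, end = 340L, tss = 98L,
                 blockSizes = "36,40", blockStarts = "0,202")
  res <- build_clusters(rbind(a, b), seeds)
  cl <- res$clusters
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 98L)
  expect_equal(cl$end, 530L)
  expect_equal(cl$score, 2)
  expect_equal(cl$name, "s1")
  expect_equal(cl$thickStart, 95L)
  expect_equal(cl$thickEnd, 105L)
  expect_equal(cl$blockSizes, "38,40,30")     # [98,136) [300,340) [500,530)
  expect_equal(cl$blockStarts, "0,202,402")
  expect_equal(nrow(res$unassigned), 0L)
})

test_that("cluster blocks equal a per-base bitmap union oracle", {
  set.seed(21)
  seeds <- load_seeds(seed_row(name = "s1", start = 0L, end = 50L))
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    recs <- do.call(rbind, lapply(seq_len(k), function(i) {
      tss <- sample.int(50L, 1) - 1L
      b2 <- tss + sample.int(400L, 1)
      bed12_row(name = paste0("m", i), start = tss, end = b2 + 30L,
                tss = tss, blockSizes = paste0("30,", 30L),
                blockStarts = paste0("0,", b2 - tss))
    }))
    # keep only structurally valid rows (second block must not precede first)
    keep <- vapply(seq_len(nrow(recs)), function(i) {
      st <- as.integer(strsplit(recs$blockStarts[i], ",")[[1]])
      st[2] >= 30L
    }, logical(1))
    recs <- recs[keep, , drop = FALSE]
    if (nrow(recs) == 0) next
    cl <- build_clusters(recs, seeds)$clusters
    # bitmap oracle
    lo <- min(recs$start); hi <- max(recs$end)
    bm <- logical(hi - lo)
    for (i in seq_len(nrow(recs))) {
      sz <- as.integer(strsplit(recs$blockSizes[i], ",")[[1]])
      st <- as.integer(strsplit(recs$blockStarts[i], ",")[[1]])
      for (j in seq_along(sz)) {
        a0 <- recs$start[i] + st[j] - lo
        bm[(a0 + 1):(a0 + sz[j])] <- TRUE
      }
    }
    r <- rle(bm)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    bs <- starts[r$values] + lo; be <- ends[r$values] + lo
    expect_equal(cl$blockSizes, paste(be - bs, collapse = ","))
    expect_equal(cl$blockStarts, paste(bs - bs[1], collapse = ","))
    expect_equal(cl$start, bs[1])
    expect_equal(cl$end, be[length(be)])
    expect_equal(cl$score, nrow(recs))
  }
})

test_that("clustering is order-independent and conserves records", {
  set.seed(33)
  seeds <- load_seeds(rbind(seed_row(name = "s1", start = 0L, end = 20L),
                            seed_row(name = "s2", start = 100L, end = 120L)))
  recs <- do.call(rbind, lapply(1:20, function(i) {
    tss <- sample(c(0:19, 100:119, 300L), 1)  # some miss all seeds
    bed12_row(name = paste0("r", i), start = tss, end = tss + 40L,
              tss = tss)
  }))
  res1 <- build_clusters(recs, seeds)
  res2 <- build_clusters(recs[sample(nrow(recs)), ], seeds)
  expect_identical(res1$clusters, res2$clusters)
  expect_equal(sum(res1$clusters$score) + nrow(res1$unassigned),
               nrow(recs))
})

test_that("meta-clusters count libraries, not pairs, and union blocks", {
  c1 <- bed12_row(name = "s1", start = 100L, end = 200L, score = 5,
                  tss = 100L)
  c1$thickStart <- 95L; c1$thickEnd <- 105L
  c2 <- bed12_row(name = "s1", start = 300L, end = 400L, score = 7,
                  tss = 300L)
  c2$thickStart <- 95L; c2$thickEnd <- 105L
  m <- merge_meta(list(libA = c1, libB = c2, libC = c1))
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 3)                    # 3 libraries, not 12 pairs
  expect_equal(m$blockCount, 2L)              # disjoint spans stay separate
  expect_equal(m$start, 100L)
  expect_equal(m$end, 400L)
  # single library: identity with score 1
  one <- merge_meta(list(libA = c1))
  expect_equal(one$score, 1)
  expect_equal(one$blockSizes, c1$blockSizes)
  # merging a library with itself: library-identity dedup keeps score 1
  self <- merge_meta(list(libA = c1, libA = c1))
  expect_equal(self$score, 1)
  # conflicting seed coordinates across libraries are an error
  c3 <- c2; c3$thickStart <- 50L
  expect_error(merge_meta(list(libA = c1, libB = c3)), "coordinates")
})

test_that("de novo seeds single-link TSSs with a strict distance bound", {
  mk <- function(tss) bed12_row(name = paste0("t", tss), start = tss,
                                end = tss + 30L, tss = tss)
  s <- de_novo_seeds(rbind(mk(100L), mk(105L), mk(300L)), 20L)
  expect_equal(s$start, c(100L, 300L))
  expect_equal(s$end, c(106L, 301L))
  expect_equal(s$name, c("chr1:100..106,+", "chr1:300..301,+"))
  # boundary: gap of exactly join_distance joins; one more splits
  s2 <- de_novo_seeds(rbind(mk(100L), mk(120L)), 20L)
  expect_equal(nrow(s2), 1L)
  s3 <- de_novo_seeds(rbind(mk(100L), mk(121L)), 20L)
  expect_equal(nrow(s3), 2L)
  # one TSS -> one 1-bp seed
  s4 <- de_novo_seeds(mk(500L), 20L)
  expect_equal(s4$end - s4$start, 1L)
  expect_error(de_novo_seeds(mk(1L), -1L), "non-negative")
  # derived seeds are a valid seed set and capture every record
  recs <- rbind(mk(100L), mk(105L), mk(300L))
  sd <- load_seeds(de_novo_seeds(recs, 20L))
  expect_false(anyNA(assign_to_seed(recs, sd)))
})
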