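---
title: "CAGEscan processing: model, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAGEscan processing: model, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagescanr)
```

## What the toolkit computes

A CAGEscan library is a set of barcoded paired-end reads in which read1
(the CAGE mate) starts at the 5′ end of a capped RNA and read2 (the
CAGEscan mate) comes from a random-primed position downstream in the same
cDNA.  After alignment, each surviving pair links a single-nucleotide TSS
to downstream gene-body evidence.  The toolkit turns raw pairs into three
artefacts:

* **pair records** — one BED12 line per proper pair, scored by the sum of
  the two mapping qualities, with the 1-bp TSS in the thick fields and
  the union of both mates' aligned segments as blocks;
* **CAGEscan clusters** — one BED12 transcript model per promoter seed
  that collected at least one pair, scored by pair count;
* a **QC ledger** that partitions every input pair into exactly one of
  Unextracted, Artefacts, rDNA, Non-aligned, Non-proper, Duplicates, or
  CAGEscanPairs.

The partition is an invariant, not a convention: `qc_ledger()` refuses to
construct or write a ledger whose categories do not sum to the total, and
the pipeline recomputes the identity at manifest time.

## Stage conventions

**Preparation.**  Read1 must begin with the sample barcode followed by
the template-switching linker; the first 9 bases of read1 (barcode +
linker) and the first 6 bases of read2 (random-primer bases, error-prone
by hybridisation) are trimmed.  The linker sequence itself varies between
protocols, so it is a configurable pattern defaulting to three wildcard
bases (`"NNN"`), while the barcode is matched strictly; this preserves
the reject-if-absent semantics without hard-coding one oligo.  Reads
shorter than their trim length are rejected, never truncated.  Quality
strings are carried through every trim but never used for filtering: the
protocol applies no quality filter, and neither do we.

**Contaminant filters.**  Artefact and rDNA screening need only a
match/no-match verdict per mate, so matching is exact-substring or
k-mismatch scanning (`Biostrings`), plus a mono-nucleotide low-complexity
rule for the artefact stage: a mate whose most frequent base reaches a
configurable fraction (default 0.9) is treated as an artefact.  rDNA
matching scans both strands, because fragments arise from either strand
of the ribosomal repeat; artefact matching is forward-only by default,
matching how primer/empty-construct contamination arises.  A pair is
removed when *either* mate fails *either* filter; a pair failing both
filters is counted once, at the artefact stage, mirroring the filter
order.

**Proper pairs.**  A pair is proper iff both mates map to the same
reference, on opposite strands with the plus-strand mate starting at or
left of the minus-strand mate (inward/FR, ties accepted), and the outer
span — `max(end) − min(start)` — is at most 2,000,000 bp, *inclusive*.
The wide bound exists so that mates falling on different exons of a gene
still pair.  Whether the original limit was measured as aligner insert
size or outer span is ambiguous; we pin outer span because it is defined
purely by the records at hand and is aligner-independent.  For the same
reason the properness bit in the input (flag 0x2) is recorded but never
trusted: the verdict is always recomputed.  Secondary and supplementary
alignments are ignored; only primary alignments are paired.

**TSS and block arithmetic.**  All coordinates are 0-based half-open.
The TSS of a minus-strand CAGE mate is its alignment end − 1 (the
rightmost genomic base is the 5′ base of the read).  BED12 blocks are the
union of the mates' reference-consuming CIGAR segments: M/=/X/D extend a
block, N splits it, and overlap or adjacency between mates merges.  The
first block is flush with chromStart, the last with chromEnd — enforced
by `validate_bed12()` on everything the package writes.

**Deduplication.**  PCR duplicates are pairs with identical
(chrom, strand, chromStart, chromEnd): of *n* such pairs, one is kept and
*n−1* are counted.  Block structure is deliberately not part of the key —
"identical coordinates" means the outer span.  The original tool's
tie-breaking is unrecorded, so ours is declared: highest score wins, then
the lexicographically smallest read name, making output reproducible
record-for-record.

**Clustering.**  Seeds are stranded promoter intervals; same-strand
overlaps in a seed set are rejected at load rather than resolved
silently, because reference peak sets are non-overlapping per strand and
an overlap indicates a data error.  A pair joins the unique same-strand
seed containing its TSS base; pairs missing every seed are written to a
separate unassigned file, never dropped silently (whether the original
clustering had a fallback for them is unrecorded).  A cluster's span
covers its members, not necessarily the whole seed, so chromStart ≤
thickStart is *not* an invariant of cluster records.  Meta-clusters merge
per-library clusters by seed name; their score counts distinct
contributing libraries, never pairs, and repeated library identifiers are
de-duplicated first.  De novo seeding single-links TSS positions at
distance ≤ `join_distance` (default 20 bp, a typical promoter-level
clustering width for CAGE signal).

**Scores vs the BED format.**  Pair counts and library counts are
unbounded, but the BED specification bounds the score field at 1000.
Writers therefore clamp scores into [0, 1000] by default
(`strict_bed = TRUE`); passing `strict_bed = FALSE` writes true counts,
at the cost of strict-BED validity.  True counts always live unclamped in
the returned data frames and the ledger.

**Detected peaks and similarity.**  A seed counts as detected in a
library when its cluster score reaches `min_pairs` (default 1 — no
stated threshold exists, so the laxest one is the default and the knob is
exposed).  Jaccard similarity between detected-peak sets is 0 when both
sets are empty (a declared convention; the ratio is otherwise 0/0), the
diagonal is 1 whenever a library detects at least one peak, and
`best_match()` breaks ties lexicographically.

## The synthetic generator

`simulate_truth()` draws a uniform-random genome and non-overlapping
spliced transcript models (1–3 exons of 150–400 bp, introns of
100–800 bp by default), each with a promoter seed peak of
`tss_peak_width` (default 10 bp) at its 5′ end.  `simulate_library()`
then emits reads: clean pairs place read1 at a TSS drawn inside the seed
and read2 at a random downstream position within a single exon — mates
may fall in different exons, in which case the intron appears as the gap
between the pair's BED12 blocks, which is precisely the association the
assay exists to capture.  Reads never straddle exon junctions, because
the alignment model is not splice-aware and the simulator emulates only
what that pipeline can see.  Contaminants are injected per pair at
configured rates: barcode-less pairs (Unextracted), mates copying an
artefact sequence or the synthetic rDNA contig, same-strand or
outward-facing alignments (Non-proper), pairs with an unmapped mate
(Non-aligned), and exact coordinate copies of existing clean pairs
(Duplicates).  The ledger type also needs a Non-aligned source, so the
generator has a `nonaligned_rate` alongside the other rates.  MAPQs come
from a small discrete set {0, 20, 30, 37} to exercise score summation
and dedup tie-breaking.

Default rates (10% unextracted, 2% artefact, 30% rDNA, 5% improper, 2%
non-aligned, 10% duplicate, 1% per-base error) follow the situation of
total-RNA 5′ libraries, where the ribosomal repeat is the dominant
contaminant and duplicate rates are appreciable but the library is not
exhausted.

Substitution errors are applied to genome-derived read bases only.
Contaminant reads carry exact artefact/rDNA sequence so that the
declared match policy (default exact) identifies them — the real
pipeline's filters tolerate mismatches through their own models, which
we do not reproduce.  Consequently passing rate-recovery tests show that
the accounting is correct, not that the matcher is error-tolerant; error
tolerance is exercised separately through the `max_mismatch` policy.

Clean pairs are drawn with globally unique outer coordinates (bounded
retries), so the expected cluster for each seed is computable exactly:
`truth_clusters()` re-derives it with a deliberately naive per-base
bitmap union, independent of the pipeline's interval algebra, and the
pipeline's output must equal it field for field.

What the generator does *not* emulate: realistic base-quality profiles,
error-driven mismapping (alignments are placed by construction, so
sequencing errors never move a read), random-primer sequence bias, and
multi-sample barcoding (one barcode per library, as in the protocol).
Passing tests therefore certify the bookkeeping, geometry and clustering
semantics of the pipeline — not robustness to alignment noise.

## Test and verification scale

The test suite runs the full pipeline on simulated experiments of 2–25
transcripts and up to 5,000 read pairs: 100 small fuzzed libraries for
the ledger partition, 50 randomized instances for oracle equivalence of
clustering, a 5,000-pair library for contamination-rate recovery (3
binomial standard deviations), four libraries from two disjoint truths
for replicate identification at 5% per-base error, and 10,000 random
mate placements against an exhaustive proper-pair oracle.  These sizes
make the properties sharp (binomial tolerances of a percent or two)
while keeping the suite quick on a laptop.

## Known limitations

* Splice-aware refinement of blocks is out of scope; an intron crossed
  *within* one mate would only be represented if the aligner emitted N
  operations, and the simulator never produces such reads.
* The artefact/rDNA matcher is a contract-level stand-in: verdicts and
  accounting are faithful, but the matching sensitivity of dedicated
  screening tools (HMM-based) is not reproduced.
* Expression quantification, normalisation and downstream atlas analyses
  are not part of the toolkit; it ends at clusters, meta-clusters, QC
  triples, annotation fractions and the similarity matrix.
* Hierarchical clustering of the similarity matrix is limited to the
  matrix itself; drawing dendrograms/heatmaps is left to standard tools
  (`stats::hclust`, `pheatmap`).
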