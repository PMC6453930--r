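test_that("three-letter read conversion substitutes C->T and G->A", {
  cv <- convert_reads("ACGT")
  expect_equal(cv$ct, "ATGT")
  expect_equal(cv$ga, "ACAT")
  cv <- convert_reads("ATTA")   # no C, no G
  expect_equal(cv$ct, "ATTA")
  expect_equal(cv$ga, "ATTA")
  expect_warning(cv <- convert_reads(c("ACGT", "")), "empty")
  expect_equal(nrow(cv), 1L)
  # postcondition over simulated reads: the ct variant is C-free
  cfg <- small_cfg(depth = 2)
  g <- simulate_genome(cfg)
  rs <- simulate_bisulfite_reads(g, simulate_methylome(g), cfg)
  cv <- convert_reads(rs)
  expect_false(any(grepl("C", cv$ct, fixed = TRUE)))
  expect_false(any(grepl("G", cv$ga, fixed = TRUE)))
})

test_that("verbatim reads align uniquely; exact duplicates are multi-mapped", {
  set.seed(41)
  seq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
               collapse = "")
  idx <- build_converted_index(c(chr1 = seq))
  read <- substr(seq, 501, 560)
  aln <- align_reads(read, idx)
  expect_equal(aln$status, "unique")
  expect_equal(aln$start, 500L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$mismatches, 0L)
  # a minus-origin read aligns to the G->A space with strand "-"
  aln <- align_reads(revcomp(read), idx)
  expect_equal(aln$status, "unique")
  expect_equal(aln$start, 500L)
  expect_equal(aln$strand, "-")
  # duplicated locus: tie at best score -> discarded
  dup <- paste0(seq, substr(seq, 501, 560),
                paste(rep("A", 40), collapse = ""))
  idx2 <- build_converted_index(c(chr1 = dup))
  aln <- align_reads(read, idx2)
  expect_equal(aln$status, "multi")
  # read shorter than the seed k-mer is unaligned
  aln <- align_reads(substr(seq, 501, 510), idx)
  expect_equal(aln$status, "unaligned")
})

test_that("usable alignments never exceed the mismatch cap", {
  cfg <- small_cfg(depth = 5, error_rate = 0.01)
  g <- simulate_genome(cfg)
  rs <- simulate_bisulfite_reads(g, simulate_methylome(g), cfg)
  idx <- build_converted_index(g)
  aln <- align_reads(rs, idx, max_mismatches = 2)
  ok <- aln$status == "unique"
  expect_true(all(aln$mismatches[ok] <= 2))
  expect_gt(mean(ok), 0.5)
})

test_that("pileup counts retention and conversion on the informative strand only", {
  genome <- c(chr = "CTCTAAAAGAGAAAAAAAAA")
  mk_aln <- function(seq, strand, start = 0L) {
    data.table::data.table(read_id = "r1", chrom = "chr", start = start,
                           strand = strand, mismatches = 0L,
                           status = "unique", seq = seq)
  }
  # "+"-origin fully converted read over genomic CTCT: conversion at 0 and 2
  p <- pileup(mk_aln("TTTT", "+"), genome)
  expect_equal(p$pos, c(0L, 2L))
  expect_equal(p$retained, c(0L, 0L))
  expect_equal(p$converted, c(1L, 1L))
  # retained read
  p <- pileup(mk_aln("CTCT", "+"), genome)
  expect_equal(p$retained, c(1L, 1L))
  expect_equal(p$converted, c(0L, 0L))
  # a "-"-origin read over GAGA (pos 8-11): genomic Gs are minus-strand Cs;
  # the read as sequenced is TCTC (fully retained revcomp)
  p <- pileup(mk_aln("TCTC", "-", 8L), genome)
  expect_equal(p$pos, c(8L, 10L))
  expect_equal(p$strand, c("-", "-"))
  expect_equal(p$retained, c(1L, 1L))
  # converted minus read reads A at G positions: TTTT revcomp'd is AAAA
  p <- pileup(mk_aln("TTTT", "-", 8L), genome)
  expect_equal(p$converted, c(1L, 1L))
  expect_equal(p$retained, c(0L, 0L))
  # a "+" read is never counted at G positions and vice versa
  p <- pileup(mk_aln("GAGA", "+", 8L), genome)
  expect_equal(nrow(p), 0L)
  # overhanging alignment violates the record invariant
  expect_error(pileup(mk_aln("CTCT", "+", 18L), genome), "overhang")
})

test_that("fully methylated simulations leave no conversion counts", {
  cfg <- small_cfg(chrom_length = 6000, te_count = 3, gene_count = 2,
                   te_size_range = c(100, 1000), organelle_length = 0,
                   depth = 5, methylation_failure_rate = 0)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g)
  m[, p := 1]
  rs <- simulate_bisulfite_reads(g, m, cfg)
  pl <- pileup(align_reads(rs, build_converted_index(g)), g)
  # context-defined cytosines retain everywhere (edge cytosines excluded)
  calls <- call_single_c(pl, g)
  expect_true(all(calls$converted == 0))
  expect_true(all(calls$level == 1))
})

test_that("seeded aligner agrees with the exhaustive scan on a small genome", {
  cfg <- small_cfg(chrom_length = 8000, te_count = 4, gene_count = 2,
                   te_size_range = c(100, 1000), organelle_length = 2000,
                   depth = 5, seed = 17)
  g <- simulate_genome(cfg)
  rs <- simulate_bisulfite_reads(g, simulate_methylome(g), cfg)
  idx <- build_converted_index(g)
  seeded <- align_reads(rs, idx)
  scan <- align_reads_scan(rs, idx)
  expect_identical(seeded$status, scan$status)
  u <- seeded$status == "unique"
  expect_identical(seeded$chrom[u], scan$chrom[u])
  expect_identical(seeded$start[u], scan$start[u])
  expect_identical(seeded$strand[u], scan$strand[u])
  expect_identical(seeded$mismatches[u], scan$mismatches[u])
  # and both recover the simulator's truth sidecar
  tr <- merge(seeded[u], rs$truth, by = "read_id")
  expect_gt(mean(tr$chrom.x == tr$chrom.y & tr$start == tr$pos &
                   tr$strand.x == tr$strand.y), 0.99)
})

test_that("retention plus conversion never exceeds local read coverage", {
  cfg <- small_cfg(chrom_length = 5000, te_count = 2, gene_count = 1,
                   te_size_range = c(100, 800), organelle_length = 0,
                   depth = 8)
  g <- simulate_genome(cfg)
  rs <- simulate_bisulfite_reads(g, simulate_methylome(g), cfg)
  aln <- align_reads(rs, build_converted_index(g))
  pl <- pileup(aln, g)
  u <- aln[aln$status == "unique", ]
  cov <- integer(cfg$chrom_length)
  for (i in seq_len(nrow(u)))
    cov[(u$start[i] + 1):(u$start[i] + nchar(u$seq[i]))] <-
      cov[(u$start[i] + 1):(u$start[i] + nchar(u$seq[i]))] + 1L
  expect_true(all(pl$retained + pl$converted <= cov[pl$pos + 1]))
})

test_that("external SAM alignments feed the same pileup", {
  cfg <- small_cfg(chrom_length = 5000, te_count = 2, gene_count = 1,
                   te_size_range = c(100, 800), organelle_length = 0,
                   depth = 3)
  g <- simulate_genome(cfg)
  rs <- simulate_bisulfite_reads(g, simulate_methylome(g), cfg)
  aln <- align_reads(rs, build_converted_index(g))
  u <- aln[aln$status == "unique", ]
  # write the internal alignments as SAM and read them back
  sam <- tempfile(fileext = ".sam")
  seqs <- u$seq
  minus <- u$strand == "-"
  seqs[minus] <- vapply(seqs[minus], revcomp, "")  # SAM stores fwd orientation
  writeLines(c(
    paste0("@HD\tVN:1.6\tSO:coordinate"),
    paste0("@SQ\tSN:chr1\tLN:", cfg$chrom_length),
    sprintf("%s\t%d\tchr1\t%d\t42\t%dM\t*\t0\t0\t%s\t*",
            u$read_id, ifelse(minus, 16L, 0L), u$start + 1L,
            nchar(seqs), seqs)), sam)
  ext <- read_sam_alignments(sam)
  expect_equal(nrow(ext), nrow(u))
  p1 <- pileup(u, g)
  p2 <- pileup(ext[order(match(ext$read_id, u$read_id))], g)
  expect_equal(p1, p2)
})
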