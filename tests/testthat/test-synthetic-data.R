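test_that("configuration invariants are enforced", {
  expect_error(sim_config(conversion_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(te_size_range = c(20, 2000)), ">= 50")
  expect_error(sim_config(chrom_length = 10000, te_size_range = c(100, 5000)),
               "chrom_length / 4")
  # infeasible packing: features exceed 80% of the genome
  expect_error(simulate_genome(sim_config(n_chromosomes = 1,
                                          chrom_length = 20000,
                                          te_count = 40, gene_count = 0,
                                          te_size_range = c(400, 800))),
               "configuration error")
})

test_that("te_count = 0 yields no TE intervals but complete tracks", {
  g <- simulate_genome(small_cfg(te_count = 0))
  expect_equal(sum(g$features$type == "TE"), 0L)
  expect_true(all(c("H3K9me2", "H3K4me3", "H3", "siRNA", "GC") %in%
                    names(g$tracks)))
  expect_false(anyNA(g$tracks$H3K9me2))
  # methylome of a TE-free genome is entirely unmethylated
  m <- simulate_methylome(g)
  expect_true(all(m$p == 0))
})

test_that("identical seeds reproduce genome, methylome and reads bit-identically", {
  cfg <- small_cfg(seed = 33)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$features, g2$features)
  expect_identical(g1$tracks, g2$tracks)
  m1 <- simulate_methylome(g1); m2 <- simulate_methylome(g2)
  expect_identical(m1$p, m2$p)
  r1 <- simulate_bisulfite_reads(g1, m1, cfg)
  r2 <- simulate_bisulfite_reads(g2, m2, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  # and a different seed gives different reads
  r3 <- simulate_bisulfite_reads(g1, m1, cfg, seed = 34)
  expect_false(identical(r1$reads$seq, r3$reads$seq))
})

test_that("features are placed without overlap and long TEs are heterochromatic", {
  g <- simulate_genome(sim_config(te_count = 50, gene_count = 10,
                                  te_size_range = c(100, 5000), seed = 9))
  f <- g$features
  for (cn in unique(f$chrom)) {
    fc <- f[f$chrom == cn, ][order(start)]
    expect_true(all(fc$start >= 0 & fc$end <= g$chrom_info$length[
      g$chrom_info$chrom == cn]))
    if (nrow(fc) > 1) expect_true(all(fc$start[-1] >= fc$end[-nrow(fc)]))
  }
  # recompute the TE-length vs H3K9me2 coupling directly from the tracks
  te <- f[f$type == "TE", ]
  k9 <- vapply(seq_len(nrow(te)), function(i) {
    w <- g$tracks[g$tracks$chrom == te$chrom[i] &
                    g$tracks$start >= te$start[i] &
                    g$tracks$start < te$end[i], ]
    mean(w$H3K9me2)
  }, numeric(1))
  expect_gt(cor(te$size, k9), 0.5)
  # euchromatic mark decreases with TE length
  k4 <- vapply(seq_len(nrow(te)), function(i) {
    w <- g$tracks[g$tracks$chrom == te$chrom[i] &
                    g$tracks$start >= te$start[i] &
                    g$tracks$start < te$end[i], ]
    mean(w$H3K4me3)
  }, numeric(1))
  expect_lt(cor(te$size, k4), 0)
})

test_that("methylome calibration hits the per-context TE means", {
  g <- simulate_genome(sim_config(seed = 21))
  base <- c(CG = 0.8, CHG = 0.7, CHH = 0.2)
  m <- simulate_methylome(g, base_levels = base)
  te <- g$features[g$features$type == "TE", ]
  inside <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(te)))
    inside <- inside | (m$chrom == te$chrom[i] & m$pos >= te$start[i] &
                          m$pos < te$end[i])
  for (cx in names(base)) {
    sel <- inside & m$context == cx
    expect_gt(sum(sel), 1e4)
    expect_lt(abs(mean(m$p[sel]) - base[[cx]]), 0.02)
  }
  # TE-restricted landscape: p = 0 outside TEs
  expect_true(all(m$p[!inside] == 0))
})

test_that("genotype effects scale the wild-type model as constructed", {
  g <- simulate_genome(small_cfg())
  wt <- simulate_methylome(g)
  expect_identical(apply_genotype_effect(wt, genotype_preset("identity"))$p,
                   wt$p)
  eff <- genotype_effect("chh-loss", r_chh = 0.05)
  mut <- apply_genotype_effect(wt, eff)
  expect_equal(mean(mut$p[mut$context == "CHH"]),
               0.05 * mean(wt$p[wt$context == "CHH"]))
  expect_identical(mut$p[mut$context != "CHH"], wt$p[wt$context != "CHH"])
  # subcontext override beats the context factor where its token matches
  eff2 <- genotype_effect("dcg", r_cg = 1, subcontext_retention = c(DCG = 0.5))
  mut2 <- apply_genotype_effect(wt, eff2)
  is_dcg <- grepl("(^|,)DCG(,|$)", wt$subcontext)
  expect_equal(mut2$p[is_dcg], 0.5 * wt$p[is_dcg])
  expect_identical(mut2$p[!is_dcg], wt$p[!is_dcg])
  # redistribution keeps probabilities in [0, 1]
  mut3 <- apply_genotype_effect(wt, genotype_preset("cmt"))
  expect_true(all(mut3$p >= 0 & mut3$p <= 1))
  expect_error(simulate_methylome(g, base_levels = c(CG = 0.8, CHG = 0.7, CXX = 0.1)),
               "context key")
})

test_that("read chemistry honours the conversion extremes", {
  cfg <- small_cfg(chrom_length = 5000, te_count = 3, gene_count = 2,
                   te_size_range = c(100, 1000), gene_size_range = c(300, 600),
                   organelle_length = 0, depth = 4)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g)
  expect_error(simulate_bisulfite_reads(g, m, small_cfg(depth = 0)), "depth")

  # p_true = 0 everywhere + full conversion: no C at any origin-strand C
  m0 <- data.table::copy(m); m0[, p := 0]
  rs <- simulate_bisulfite_reads(g, m0, small_cfg(chrom_length = 5000,
    te_count = 3, gene_count = 2, te_size_range = c(100, 1000),
    gene_size_range = c(300, 600), organelle_length = 0, depth = 4,
    conversion_rate = 1))
  expect_false(any(grepl("C", rs$reads$seq, fixed = TRUE)))

  # p_true = 1 everywhere + no failures: reads copy the genome exactly
  m1 <- data.table::copy(m); m1[, p := 1]
  cfg1 <- small_cfg(chrom_length = 5000, te_count = 3, gene_count = 2,
                    te_size_range = c(100, 1000), gene_size_range = c(300, 600),
                    organelle_length = 0, depth = 4,
                    methylation_failure_rate = 0)
  rs1 <- simulate_bisulfite_reads(g, m1, cfg1)
  origin <- substring(g$seq[rs1$truth$chrom], rs1$truth$pos + 1,
                      rs1$truth$pos + cfg1$read_length)
  minus <- rs1$truth$strand == "-"
  origin[minus] <- vapply(origin[minus], revcomp, "")
  # chromosome-edge cytosines have undefined context, carry no model record
  # and default to unmethylated, so skip reads touching the last two bases
  clen <- g$chrom_info$length[match(rs1$truth$chrom, g$chrom_info$chrom)]
  interior <- rs1$truth$pos >= 2 & rs1$truth$pos + cfg1$read_length <= clen - 2
  expect_true(any(interior))
  expect_identical(rs1$reads$seq[interior], unname(origin[interior]))
})

test_that("read count and conservation match the sampling model", {
  cfg <- small_cfg(depth = 10)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g)
  rs <- simulate_bisulfite_reads(g, m, cfg)
  total <- sum(g$chrom_info$length)
  expect_lt(abs(nrow(rs$reads) - cfg$depth * total / cfg$read_length),
            3 * sqrt(cfg$depth * total / cfg$read_length))
  # conservation: reads differ from their origin-strand substring only at
  # cytosine positions of that strand
  origin <- substring(g$seq[rs$truth$chrom], rs$truth$pos + 1,
                      rs$truth$pos + cfg$read_length)
  minus <- rs$truth$strand == "-"
  origin[minus] <- vapply(origin[minus], revcomp, "")
  for (i in sample(nrow(rs$reads), 200)) {
    ob <- strsplit(origin[i], "", fixed = TRUE)[[1]]
    rb <- strsplit(rs$reads$seq[i], "", fixed = TRUE)[[1]]
    diff <- which(ob != rb)
    expect_true(all(ob[diff] == "C" & rb[diff] == "T"))
  }
})
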