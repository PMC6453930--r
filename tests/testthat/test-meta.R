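test_that("TE metaplots pool per-cytosine levels by 5'-anchored intervals", {
  # uniform levels give a flat profile
  tes <- data.frame(chrom = "chr1", start = c(100L, 600L),
                    end = c(350L, 1400L), strand = c("+", "-"),
                    type = "TE", id = c("te1", "te2"))
  pos <- c(110, 150, 210, 300, 340, 650, 700, 900, 1300)
  calls <- toy_calls("chr1", pos, "+", "CHH", 5, 5)
  mp <- te_metaplot(calls, tes)
  expect_true(all(mp$mean_level == 0.5))
  # a 250-bp TE contributes nothing beyond offset 200
  mp1 <- te_metaplot(calls, tes[1, ])
  expect_true(all(mp1$offset <= 200))
  # hand-built two-TE profile equals brute-force pooling
  lv <- seq(0.1, 0.9, length.out = length(pos))
  calls2 <- toy_calls("chr1", pos, "+", "CHH", round(lv * 100),
                      100 - round(lv * 100))
  mp2 <- te_metaplot(calls2, tes, interval = 100)
  brute <- list()
  for (i in seq_along(pos)) for (j in 1:2) {
    if (pos[i] >= tes$start[j] && pos[i] < tes$end[j]) {
      off <- if (tes$strand[j] == "+") pos[i] - tes$start[j]
             else (tes$end[j] - 1) - pos[i]
      key <- as.character((off %/% 100) * 100)
      brute[[key]] <- c(brute[[key]], calls2$level[i])
    }
  }
  for (k in names(brute))
    expect_equal(mp2$mean_level[mp2$offset == as.integer(k)],
                 mean(brute[[k]]))
  # empty annotation: explicit empty result
  expect_equal(nrow(te_metaplot(calls, tes[0, ])), 0L)
})

test_that("the metaplot flank extends upstream of the alignment point", {
  tes <- data.frame(chrom = "chr1", start = 500L, end = 800L, strand = "+",
                    type = "TE", id = "te1")
  calls <- toy_calls("chr1", c(450, 520), "+", "CHH", c(9, 1), c(1, 9))
  mp <- te_metaplot(calls, tes, flank = 100)
  expect_equal(mp$offset, c(-100L, 0L))
  expect_equal(mp$mean_level, c(0.9, 0.1))
})

test_that("TE-edge frequencies upstream of TSS follow the closest-facing-edge rule", {
  # TE ending 10 bp upstream of a + gene: first 25-bp window only
  genes <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                      strand = "+", type = "gene", id = "g1")
  tes <- data.frame(chrom = "chr1", start = 500L, end = 991L, strand = "+",
                    type = "TE", id = "t1")
  h <- te_tss_histogram(genes, tes)
  expect_equal(h$percent[h$offset == 0], 100)
  expect_equal(sum(h$n_genes), 1L)
  # no TEs: all windows 0%
  h0 <- te_tss_histogram(genes, tes[0, ])
  expect_true(all(h0$percent == 0))
  expect_error(te_tss_histogram(transform(genes, strand = "*"), tes),
               "stranded")

  # toy genome: 4 genes (both strands), 3 TEs; brute-force enumeration
  genes <- data.frame(chrom = "chr1",
                      start = c(1000L, 3000L, 5000L, 7000L),
                      end = c(1900L, 3900L, 5900L, 7900L),
                      strand = c("+", "-", "+", "-"),
                      type = "gene", id = paste0("g", 1:4))
  tes <- data.frame(chrom = "chr1",
                    start = c(700L, 3950L, 4620L),
                    end = c(960L, 4200L, 4990L),
                    strand = "+", type = "TE", id = paste0("t", 1:3))
  h <- te_tss_histogram(genes, tes, window = 25, upstream = 500)
  brute <- integer(20)
  for (i in 1:4) {
    ds <- integer()
    for (j in 1:3) {
      if (genes$strand[i] == "+") d <- genes$start[i] - (tes$end[j] - 1)
      else d <- tes$start[j] - (genes$end[i] - 1)
      if (d >= 1 && d <= 500) ds <- c(ds, d)
    }
    if (length(ds)) {
      w <- (min(ds) - 1) %/% 25 + 1
      brute[w] <- brute[w] + 1L
    }
  }
  expect_equal(h$n_genes, brute)
  expect_equal(h$percent, 100 * brute / 4)
  # closest-edge-only: each gene counted at most once
  expect_true(sum(h$n_genes) <= nrow(genes))
})

test_that("centile stratification balances groups and routes no-signal windows to ND", {
  # strictly increasing feature, 5 centiles: 20 windows each
  st <- stratify_quantiles(rnorm(100), seq_len(100), centile_scheme("f", 5))
  expect_equal(as.integer(table(st$assignment$group)[paste0("Q", 1:5)]),
               rep(20L, 5))
  # constant feature: everything in the lowest centile, no error
  st <- stratify_quantiles(rnorm(10), rep(1, 10), centile_scheme("f", 5))
  expect_true(all(st$assignment$group == "Q1"))
  # histone scheme: log2 ratio over H3, ND when any signal is absent
  vals <- rnorm(6)
  k9 <- c(2, 4, 0, 1, 8, 2); h3 <- c(1, 1, 1, 0, 1, 1)
  st <- stratify_quantiles(vals, k9, centile_scheme("H3K9me2", 2, histone = TRUE),
                           h3 = h3)
  expect_equal(st$assignment$group[3], "ND")
  expect_equal(st$assignment$group[4], "ND")
  expect_false(any(st$assignment$group[c(1, 2, 5, 6)] == "ND"))
  # union of groups covers all windows
  expect_false(anyNA(st$assignment$group))
  # box statistics match direct computation for one group
  v1 <- st$assignment$value[st$assignment$group == "Q1"]
  expect_equal(st$summary$median[st$summary$group == "Q1"],
               stats::median(v1))
  expect_error(stratify_quantiles(1:3, 1:4, centile_scheme("f", 5)), "align")
})

test_that("correlation matrices are Pearson with pairwise-complete windows", {
  x <- data.frame(a = c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10))
  x$b <- -x$a
  suppressWarnings({
    r <- correlation_matrix(cbind(x, c = rnorm(10)))
  })
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r["a", "b"], -1)
  # hand table vs the textbook formula
  set.seed(2)
  u <- rnorm(10); v <- 2 * u + rnorm(10)
  manual <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  suppressWarnings(r2 <- correlation_matrix(data.frame(u = u, v = v)))
  expect_equal(r2["u", "v"], manual)
  # zero variance is flagged as NA
  expect_warning(r3 <- correlation_matrix(data.frame(a = 1:5, b = rep(2, 5))),
                 "undefined")
  expect_true(is.na(r3["a", "b"]))
})

test_that("siRNA/methylation/TE overlap counts follow the explicit rules", {
  tes <- data.frame(chrom = "chr1", start = seq(0L, 4500L, by = 500L),
                    end = seq(0L, 4500L, by = 500L) + 400L, strand = "+",
                    type = "TE", id = sprintf("t%02d", 1:10))
  # 4 methylated TEs (first four), siRNA on 2 of those
  calls <- toy_calls("chr1", seq(100L, 4600L, by = 500L), "+", "CHH",
                     c(rep(8L, 4), rep(0L, 6)), 2L)
  sirna <- data.frame(chrom = "chr1", start = c(0L, 500L),
                      end = c(50L, 550L), siRNA = c(10L, 10L))
  ov <- overlap_summary(sirna, calls, tes, meth_min_level = 0.5,
                        sirna_min_count = 5)
  expect_equal(ov$n_te, 10L)
  expect_equal(ov$n_methylated, 4L)
  expect_equal(ov$n_both, 2L)
  expect_equal(ov$percent_methylated_with_sirna, 50)
  # siRNA everywhere: 100%; empty track: 0%
  all_sirna <- data.frame(chrom = "chr1", start = 0L, end = 5000L,
                          siRNA = 1000L)
  expect_equal(overlap_summary(all_sirna, calls, tes, meth_min_level = 0.5,
                               sirna_min_count = 5)$percent_methylated_with_sirna,
               100)
  expect_equal(overlap_summary(sirna[0, ], calls, tes, meth_min_level = 0.5,
                               sirna_min_count = 5)$percent_methylated_with_sirna,
               0)
  expect_error(overlap_summary(sirna, calls, tes), "explicit")
})

test_that("chromosome profiles are binned means with LOWESS smoothing", {
  # constant methylation: smooth profile constant
  calls <- toy_calls("chr1", seq(0L, 99999L, by = 97L), "+", "CHH", 3, 7)
  pr <- chromosome_profile(calls, "chr1", bin = 10000L, span = 0.5)
  expect_true(all(abs(pr$smooth - 0.3) < 1e-12))
  # single-bin chromosome: identity
  pr1 <- chromosome_profile(calls[calls$pos < 5000, ], "chr1", bin = 100000L)
  expect_equal(nrow(pr1), 1L)
  expect_equal(pr1$smooth, pr1$mean_level)
  # monotone gradient stays monotone after local-linear smoothing
  pos <- seq(0L, 99999L, by = 23L)
  ret <- round(100 * (pos / 1e5))
  calls2 <- toy_calls("chr1", pos, "+", "CHH", ret, 100L - ret)
  pr2 <- chromosome_profile(calls2, "chr1", bin = 5000L, span = 0.3)
  expect_true(all(diff(pr2$smooth) > -1e-9))
  expect_error(chromosome_profile(calls2, "chrX"), "no calls")
})
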