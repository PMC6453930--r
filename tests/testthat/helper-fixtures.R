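# Shared fixtures and independent oracles, built in code at test time.

# small simulation configuration for fast unit tests
small_cfg <- function(...) {
  args <- list(n_chromosomes = 1, chrom_length = 20000, te_count = 8,
               gene_count = 4, te_size_range = c(100, 2000),
               organelle_length = 5000, seed = 7)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# hand-built single-c table from per-cytosine counts
toy_calls <- function(chrom, pos, strand, context, retained, converted,
                      subcontext = "") {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               strand = strand, context = context,
                               subcontext = subcontext,
                               retained = as.integer(retained),
                               converted = as.integer(converted))
  dt$level <- dt$retained / (dt$retained + dt$converted)
  data.table::setattr(dt, "class", c("single_c", class(dt)))
  dt
}

# two-sided Fisher oracle: exhaustive hypergeometric enumeration over all
# 2x2 tables with the observed margins (sum probabilities not exceeding the
# observed table's, with the same relative tolerance fisher.test documents)
fisher_oracle <- function(r1, c1, r2, c2) {
  m <- r1 + c1          # sample-1 total
  n <- r2 + c2          # sample-2 total
  k <- r1 + r2          # retained margin
  x <- seq(max(0L, k - n), min(k, m))
  probs <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(r1, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# reverse complement for strand-symmetry checks
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}
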