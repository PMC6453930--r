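#' Simulate a toy genome with TE/gene annotations and chromatin tracks
#'
#' Generates named chromosomes of A/C/G/T, embeds non-overlapping
#' transposable elements (TEs) and genes, and emits 50-bp chromatin tracks
#' (H3K9me2, H3K4me3, total H3, 24-nt siRNA counts, GC fraction). The
#' simulated chromatin mirrors the heterochromatin/TE-size coupling of plant
#' genomes: long TEs are placed in GC-richer neighbourhoods and carry more
#' H3K9me2 and less H3K4me3 than short TEs; siRNA counts concentrate on
#' long/heterochromatic TEs with a small euchromatic fraction. When
#' `organelle_length > 0` an unmethylated organelle-like control chromosome
#' `"chrC"` (compartment `"organelle"`) is appended; it carries no features.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: a list with elements
#'   `seq` (named character vector), `chrom_info` (`chrom`, `length`,
#'   `compartment`), `features` (0-based half-open intervals with `strand`,
#'   `type` = `"TE"`/`"gene"`, `id`, `size`), `tracks` (per 50-bp window),
#'   and the `config`.
#' @export
#' @examples
#' g <- simulate_genome(sim_config(n_chromosomes = 1, chrom_length = 20000,
#'                                 te_count = 8, gene_count = 4,
#'                                 te_size_range = c(100, 2000)))
#' nrow(g$features)
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  len <- config$chrom_length
  chroms <- paste0("chr", seq_len(nchr))

  # feasibility is a property of the configuration: expected feature load
  # must not exceed 80% of the nuclear genome
  lu_mean <- function(a, b) if (b > a) (b - a) / log(b / a) else a
  expected <- config$te_count * lu_mean(config$te_size_range[1],
                                        config$te_size_range[2]) +
    config$gene_count * mean(config$gene_size_range)
  if (expected > 0.8 * nchr * len)
    stop("configuration error: total feature length exceeds 80% of the genome")
  draw_sizes <- function() {
    te <- if (config$te_count > 0)
      round(exp(runif(config$te_count, log(config$te_size_range[1]),
                      log(config$te_size_range[2])))) else integer()
    gene <- if (config$gene_count > 0)
      round(runif(config$gene_count, config$gene_size_range[1],
                  config$gene_size_range[2])) else integer()
    list(te = te, gene = gene)
  }
  # a feasible configuration can still overshoot on an unlucky draw of the
  # heavy-tailed TE sizes; redraw (deterministically under the seed)
  for (try in 1:100) {
    sz <- draw_sizes()
    if (sum(sz$te) + sum(sz$gene) <= 0.8 * nchr * len) break
    if (try == 100)
      stop("configuration error: total feature length exceeds 80% of the genome")
  }
  te_sizes <- sz$te
  gene_sizes <- sz$gene
  feat <- data.table(
    type = c(rep("TE", length(te_sizes)), rep("gene", length(gene_sizes))),
    id = c(sprintf("TE_%03d", seq_along(te_sizes)),
           sprintf("gene_%03d", seq_along(gene_sizes))),
    size = c(te_sizes, gene_sizes))

  # greedy packing: largest feature to the emptiest chromosome
  free <- setNames(rep(len, nchr), chroms)
  feat <- feat[order(-feat$size), ]
  feat$chrom <- NA_character_
  for (i in seq_len(nrow(feat))) {
    cn <- names(which.max(free))
    if (free[cn] < feat$size[i])
      stop("configuration error: cannot pack features into chromosomes")
    feat$chrom[i] <- cn
    free[cn] <- free[cn] - feat$size[i]
  }

  # random non-overlapping placement per chromosome (stick-breaking gaps)
  placed <- lapply(chroms, function(cn) {
    f <- feat[feat$chrom == cn, ]
    if (nrow(f) == 0L) return(f[, c("chrom", "type", "id", "size")])
    f <- f[sample.int(nrow(f)), ]
    slack <- len - sum(f$size)
    cuts <- sort(runif(nrow(f)))
    gaps <- floor(diff(c(0, cuts, 1)) * slack)
    f$start <- cumsum(gaps[-length(gaps)]) + cumsum(c(0, head(f$size, -1)))
    f$end <- f$start + f$size
    f
  })
  features <- rbindlist(placed, fill = TRUE)
  if (nrow(features)) {
    features[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    setorder(features, chrom, start)
    features <- features[, .(chrom, start = as.integer(start),
                             end = as.integer(end), strand, type, id,
                             size = as.integer(size))]
  } else {
    features <- data.table(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           type = character(), id = character(),
                           size = integer())
  }

  # sequence: background GC everywhere, then TE neighbourhoods re-drawn at a
  # GC level increasing with TE size (long TEs sit in GC-richer sequence)
  seqs <- vapply(chroms, function(cn) random_seq(len, config$gc_content), "")
  te <- features[features$type == "TE", ]
  if (nrow(te)) {
    s <- te_size_score(te$size, config$te_size_range)
    for (i in seq_len(nrow(te))) {
      gc_i <- min(0.9, config$gc_content + 0.25 * s[i])
      lo <- max(0L, te$start[i] - 150L)
      hi <- min(len, te$end[i] + 150L)
      substr(seqs[te$chrom[i]], lo + 1L, hi) <- random_seq(hi - lo, gc_i)
    }
  }

  chrom_info <- data.table(chrom = chroms, length = len, compartment = "nuclear")
  if (config$organelle_length > 0) {
    seqs <- c(seqs, chrC = random_seq(config$organelle_length, config$gc_content))
    chrom_info <- rbind(chrom_info,
                        data.table(chrom = "chrC",
                                   length = config$organelle_length,
                                   compartment = "organelle"))
  }

  tracks <- simulate_tracks(seqs, chrom_info, features, config)
  structure(list(seq = seqs, chrom_info = chrom_info, features = features,
                 tracks = tracks, config = config),
            class = "sim_genome")
}

random_seq <- function(n, gc) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# 0..1 score of a TE's size on the configured log scale
te_size_score <- function(size, size_range) {
  lo <- log(size_range[1]); hi <- log(size_range[2])
  if (hi <= lo) return(rep(0.5, length(size)))
  pmin(1, pmax(0, (log(size) - lo) / (hi - lo)))
}

# 50-bp window tracks; heterochromatic marks scale with TE size, euchromatic
# marks with genes and short TEs; rare zero-signal windows feed the ND class
simulate_tracks <- function(seqs, chrom_info, features, config, window = 50L) {
  out <- lapply(seq_len(nrow(chrom_info)), function(ci) {
    cn <- chrom_info$chrom[ci]
    clen <- chrom_info$length[ci]
    starts <- seq.int(0L, clen - 1L, by = window)
    ends <- pmin(starts + window, clen)
    mids <- (starts + ends) / 2
    n <- length(starts)

    f <- features[features$chrom == cn, ]
    te_idx <- match_interval(mids, f[f$type == "TE", ])
    gene_idx <- match_interval(mids, f[f$type == "gene", ])
    te_size <- f[f$type == "TE", ]$size[te_idx]
    te_id <- f[f$type == "TE", ]$id[te_idx]
    s <- ifelse(is.na(te_size), 0,
                te_size_score(te_size, config$te_size_range))
    in_te <- !is.na(te_size)
    in_gene <- !is.na(gene_idx)

    h3 <- rgamma(n, shape = 8, rate = 8)
    k9 <- (0.1 + ifelse(in_te, 0.3 + 1.7 * s, 0)) * rlnorm(n, 0, 0.25)
    k4 <- (0.4 + ifelse(in_gene, 1.2, 0) + ifelse(in_te, 1.0 * (1 - s), 0)) *
      rlnorm(n, 0, 0.25)
    sirna <- rpois(n, lambda = 0.05 + ifelse(in_te, 0.3 + 6 * s^2, 0))
    # sparse signal dropout (independent per mark) -> ND category downstream
    h3[runif(n) < 0.02] <- 0
    k9[runif(n) < 0.02] <- 0
    k4[runif(n) < 0.02] <- 0

    gc <- window_gc(seqs[[cn]], starts, ends)
    data.table(chrom = cn, start = starts, end = ends, GC = gc,
               H3K9me2 = k9, H3K4me3 = k4, H3 = h3, siRNA = sirna,
               te_id = te_id, te_size = te_size)
  })
  rbindlist(out)
}

# index of the interval (rows of `f`, 0-based half-open) containing each point
match_interval <- function(points, f) {
  if (nrow(f) == 0L) return(rep(NA_integer_, length(points)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = as.integer(floor(points)) + 1L, width = 1L),
    IRanges::IRanges(start = f$start + 1L, end = f$end),
    select = "first")
  as.integer(hits)
}

window_gc <- function(seq, starts, ends) {
  pieces <- substring(seq, starts + 1L, ends)
  gc <- vapply(strsplit(pieces, "", fixed = TRUE),
               function(b) mean(b %in% c("G", "C")), numeric(1))
  gc
}
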