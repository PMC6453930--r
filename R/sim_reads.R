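#' Simulate single-end bisulfite reads with a truth sidecar
#'
#' Draws reads uniformly from both strands of every chromosome and applies
#' strand-specific bisulfite chemistry to the origin-strand sequence: each
#' cytosine covered by a read is methylated with its model probability
#' `p_true`; unmethylated cytosines are sequenced as T with probability
#' `conversion_rate`, methylated cytosines as T with probability
#' `methylation_failure_rate`. Apart from the chemistry (and the optional
#' uniform substitution `error_rate`) reads copy the genome, so a read
#' differs from its origin-strand substring only at cytosine positions.
#'
#' @param genome a [simulate_genome()] result.
#' @param methylome a [simulate_methylome()] model covering the genome.
#' @param config the [sim_config()] (depth, read length, chemistry rates).
#' @param seed seed for this draw; defaults to `config$seed`. Pass different
#'   seeds to obtain independent replicate read sets from one methylome.
#' @return an object of class `read_set`: list with `reads` (`read_id`,
#'   `seq`, `qual`) and `truth` (`read_id`, `chrom`, `pos` 0-based origin
#'   start on the forward coordinate frame, `strand` of origin).
#' @export
simulate_bisulfite_reads <- function(genome, methylome, config,
                                     seed = config$seed) {
  stopifnot(inherits(genome, "sim_genome"), inherits(methylome, "methylome_model"))
  if (config$depth <= 0) stop("depth must be > 0")
  L <- config$read_length
  set.seed(seed)

  info <- genome$chrom_info
  usable <- info$length - L + 1L
  if (any(usable < 1L)) stop("read_length exceeds a chromosome length")
  n_reads <- round(config$depth * sum(info$length) / L)
  ci <- sample.int(nrow(info), n_reads, replace = TRUE, prob = usable)
  start <- floor(runif(n_reads) * usable[ci])
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)

  # per-chromosome p_true lookup, concatenated with offsets
  offs <- cumsum(c(0, head(info$length, -1)))
  names(offs) <- info$chrom
  p_plus <- numeric(sum(info$length))
  p_minus <- numeric(sum(info$length))
  mp <- methylome[strand == "+"]
  p_plus[offs[mp$chrom] + mp$pos + 1L] <- mp$p
  mm <- methylome[strand == "-"]
  p_minus[offs[mm$chrom] + mm$pos + 1L] <- mm$p

  # origin-strand sequence for every read
  chrom <- info$chrom[ci]
  fwd <- substring(genome$seq[chrom], start + 1L, start + L)
  minus <- strand == "-"
  origin <- fwd
  if (any(minus)) origin[minus] <- .cpp_revcomp(fwd[minus])

  glob <- offs[chrom] + start  # 0-based global offset of read start
  cols <- vector("list", L)
  for (j in seq_len(L)) {
    b <- substring(origin, j, j)
    gpos <- ifelse(minus, glob + L - j, glob + j - 1L)
    is_c <- b == "C"
    if (any(is_c)) {
      pj <- ifelse(minus[is_c], p_minus[gpos[is_c] + 1L], p_plus[gpos[is_c] + 1L])
      meth <- runif(sum(is_c)) < pj
      u <- runif(sum(is_c))
      to_t <- (meth & u < config$methylation_failure_rate) |
        (!meth & u < config$conversion_rate)
      bc <- b[is_c]
      bc[to_t] <- "T"
      b[is_c] <- bc
    }
    cols[[j]] <- b
  }
  if (config$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(L)) {
      hit <- runif(n_reads) < config$error_rate
      if (any(hit)) {
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        old <- match(cols[[j]][hit], bases)
        old[is.na(old)] <- 1L
        cols[[j]][hit] <- bases[((old - 1L + shift) %% 4L) + 1L]
      }
    }
  }
  seqs <- do.call(paste0, cols)

  ids <- sprintf("read_%07d", seq_len(n_reads))
  structure(list(
    reads = data.table(read_id = ids, seq = seqs, qual = strrep("I", L)),
    truth = data.table(read_id = ids, chrom = chrom, pos = as.integer(start),
                       strand = strand),
    config = config),
    class = "read_set")
}
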