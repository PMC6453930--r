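#' Three-letter read conversion
#'
#' Produces the two reduced-alphabet variants used for bisulfite alignment:
#' variant `ct` replaces every C with T (the forward-read conversion) and
#' variant `ga` replaces every G with A (the reverse-read conversion). The
#' original sequences are retained for the pileup step. Empty reads are
#' skipped with a warning.
#'
#' @param reads character vector of read sequences (A/C/G/T/N), or a
#'   `read_set`.
#' @return a `data.table` with columns `read_id`, `seq` (original), `ct`,
#'   `ga`.
#' @export
#' @examples
#' convert_reads("ACGT")  # ct "ATGT", ga "ACAT"
convert_reads <- function(reads) {
  if (inherits(reads, "read_set")) {
    ids <- reads$reads$read_id
    seqs <- reads$reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- if (!is.null(names(seqs)) && all(nzchar(names(seqs)))) names(seqs)
           else sprintf("read_%07d", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning(sum(empty), " empty read(s) skipped")
    seqs <- seqs[!empty]; ids <- ids[!empty]
  }
  data.table(read_id = ids, seq = seqs,
             ct = chartr("C", "T", seqs), ga = chartr("G", "A", seqs))
}

#' Build a converted reference index
#'
#' Holds the two converted reference copies (forward copy with C->T for
#' "+"-origin reads; G->A copy for "-"-origin reads, which are matched as
#' the G->A conversion of their reverse complement) in one forward
#' coordinate frame. The k-mer seed tables themselves are built inside the
#' aligner call.
#'
#' @param genome named character vector of chromosome sequences or a
#'   `sim_genome`.
#' @param k seed k-mer length (<= 31).
#' @return an object of class `converted_index`.
#' @export
build_converted_index <- function(genome, k = 20L) {
  seqs <- as_genome_seqs(genome)
  if (k < 8L || k > 31L) stop("seed k must lie in [8, 31]")
  structure(list(chrom = names(seqs),
                 lengths = nchar(seqs),
                 ref_ct = unname(chartr("C", "T", seqs)),
                 ref_ga = unname(chartr("G", "A", seqs)),
                 genome = unname(seqs),
                 k = as.integer(k)),
            class = "converted_index")
}

#' Align converted bisulfite reads
#'
#' Seed-and-extend three-letter alignment: the first `k` bases of each
#' converted read are looked up exactly in the k-mer table of each converted
#' reference space and candidates are extended without gaps, counting
#' mismatches in converted space. Each read keeps at most one usable
#' alignment — the unique lowest-mismatch hit across both spaces within
#' `max_mismatches`; reads whose best score is tied at different loci are
#' discarded as multi-mapped; a hit in the C->T space implies origin strand
#' `"+"`, in the G->A space `"-"`. Reads shorter than `k` are unaligned.
#'
#' @param reads output of [convert_reads()] or a `read_set`.
#' @param index a [build_converted_index()].
#' @param max_mismatches maximum mismatches of a usable alignment.
#' @param method `"seeded"` (default) or `"scan"`, the exhaustive
#'   full-scan reference algorithm that scores every position of both
#'   spaces (slow; intended for validation at small genome sizes).
#' @return a `data.table` of alignment records: `read_id`, `chrom`, `start`
#'   (0-based), `strand`, `mismatches`, `status`
#'   (`unique`/`multi`/`unaligned`), `seq` (original read sequence).
#' @export
align_reads <- function(reads, index, max_mismatches = 2L,
                        method = c("seeded", "scan")) {
  method <- match.arg(method)
  stopifnot(inherits(index, "converted_index"))
  if (!is.data.frame(reads)) reads <- convert_reads(reads)
  res <- if (method == "seeded") {
    .cpp_align_seeded(index$ref_ct, index$ref_ga, index$chrom, reads$ct,
                      index$k, as.integer(max_mismatches))
  } else {
    .cpp_align_scan(index$ref_ct, index$ref_ga, index$chrom, reads$ct,
                    as.integer(max_mismatches))
  }
  out <- data.table(read_id = reads$read_id,
                    chrom = index$chrom[res$chrom_idx],
                    start = res$start,
                    strand = res$strand,
                    mismatches = res$mismatches,
                    status = res$status,
                    seq = reads$seq)
  out[]
}

#' Exhaustive full-scan alignment
#'
#' Convenience wrapper for `align_reads(..., method = "scan")`: scores every
#' start position of every chromosome in both converted spaces and applies
#' the same unique-best rule. Used as the reference algorithm the seeded
#' aligner is validated against.
#'
#' @inheritParams align_reads
#' @return see [align_reads()].
#' @export
align_reads_scan <- function(reads, index, max_mismatches = 2L) {
  align_reads(reads, index, max_mismatches, method = "scan")
}

#' Per-cytosine pileup from usable alignments
#'
#' Counts, for every genomic cytosine on either strand, the reads showing
#' retention (C for "+"-strand cytosines; G for "-"-strand cytosines, which
#' appear as G on the forward reference) and conversion (T respectively A).
#' Only reads of the informative strand contribute: a "+"-origin read is
#' counted at forward C positions only, a "-"-origin read at forward G
#' positions only.
#'
#' @param alignments output of [align_reads()] (rows with `status !=
#'   "unique"` are ignored).
#' @param genome named character vector of chromosome sequences or
#'   `sim_genome`.
#' @return a `data.table`: `chrom`, `pos` (0-based), `strand` (strand of the
#'   cytosine), `retained`, `converted`; rows with zero total are absent.
#' @export
pileup <- function(alignments, genome) {
  seqs <- as_genome_seqs(genome)
  use <- alignments[alignments$status == "unique", ]
  if (nrow(use) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), retained = integer(),
                      converted = integer()))
  oriented <- use$seq
  minus <- use$strand == "-"
  if (any(minus)) oriented[minus] <- .cpp_revcomp(oriented[minus])
  res <- .cpp_pileup(unname(seqs), match(use$chrom, names(seqs)),
                     use$start, use$strand, oriented)
  out <- lapply(seq_along(seqs), function(ci) {
    r <- res[[ci]]
    plus_pos <- which(r$ret_plus > 0L | r$conv_plus > 0L)
    minus_pos <- which(r$ret_minus > 0L | r$conv_minus > 0L)
    rbindlist(list(
      data.table(chrom = names(seqs)[ci], pos = plus_pos - 1L, strand = "+",
                 retained = r$ret_plus[plus_pos],
                 converted = r$conv_plus[plus_pos]),
      data.table(chrom = names(seqs)[ci], pos = minus_pos - 1L, strand = "-",
                 retained = r$ret_minus[minus_pos],
                 converted = r$conv_minus[minus_pos])))
  })
  out <- rbindlist(out)
  setorder(out, chrom, pos, strand)
  out[]
}
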