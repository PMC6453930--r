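#' Import alignments from an external bisulfite aligner
#'
#' Reads a SAM/BAM file produced by an external bisulfite aligner and
#' converts it to the package's alignment-record table, bypassing
#' [align_reads()]. The FLAG 0x10 bit is taken as the origin strand of a
#' directional library; since SAM stores minus-strand reads
#' reverse-complemented, those sequences are flipped back so the `seq`
#' column always holds the read as sequenced. Unmapped records are kept
#' with status `"unaligned"`; records an aligner marked secondary or
#' supplementary (0x100/0x800) are dropped.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @return alignment records as from [align_reads()] (the `mismatches`
#'   column is `NA`; external aligners apply their own threshold).
#' @export
read_sam_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE, overwrite = TRUE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "seq")))[[1]]
  drop <- bitwAnd(b$flag, 0x100L) > 0 | bitwAnd(b$flag, 0x800L) > 0
  unmapped <- bitwAnd(b$flag, 0x4L) > 0
  minus <- bitwAnd(b$flag, 0x10L) > 0
  seqs <- as.character(b$seq)
  if (any(minus & !unmapped))
    seqs[minus & !unmapped] <- .cpp_revcomp(seqs[minus & !unmapped])
  out <- data.table(read_id = b$qname,
                    chrom = as.character(b$rname),
                    start = b$pos - 1L,
                    strand = fifelse(unmapped, NA_character_,
                                     fifelse(minus, "-", "+")),
                    mismatches = NA_integer_,
                    status = fifelse(unmapped, "unaligned", "unique"),
                    seq = seqs)
  out[!drop]
}
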