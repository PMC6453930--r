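#' Read and write standard genomics formats
#'
#' Thin wrappers around Biostrings and rtracklayer that normalise all
#' coordinates to the package's internal convention: 0-based half-open
#' intervals. GFF3 (1-based inclusive) and BED/bedGraph (0-based half-open)
#' are converted accordingly on both read and write; strands are preserved.
#' FASTA sequences are uppercased with N kept.
#'
#' @param path file path.
#' @return `read_fasta()`: named uppercase character vector.
#' @name io-formats
NULL

#' @rdname io-formats
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname io-formats
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname io-formats
#' @return `read_fastq()`: `data.table` with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on FASTQ input
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.table(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)))
}

#' @rdname io-formats
#' @param reads a `read_set` or `data.table` with `read_id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual),
             con)
  invisible(path)
}

#' @rdname io-formats
#' @return `read_gff()`: `data.table` with 0-based half-open `chrom`,
#'   `start`, `end`, `strand`, `type`, `id`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_along(gr))
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    type = as.character(gr$type),
                    id = id)
  out[out$strand == "*", "strand"] <- "+"
  out[]
}

#' @rdname io-formats
#' @param features 0-based half-open annotation `data.frame` (`chrom`,
#'   `start`, `end`, `strand`, `type`, `id`).
#' @export
write_gff <- function(features, path) {
  f <- as.data.table(features)
  gr <- GenomicRanges::GRanges(f$chrom,
                               IRanges::IRanges(start = f$start + 1L, end = f$end),
                               strand = f$strand)
  gr$type <- f$type
  gr$ID <- f$id
  gr$source <- "mossmeth"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname io-formats
#' @return `read_bedgraph()`: `data.table` with 0-based half-open `chrom`,
#'   `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' @rdname io-formats
#' @param track `data.frame` with 0-based half-open `chrom`, `start`, `end`
#'   and a numeric value column (last column used).
#' @export
write_bedgraph <- function(track, path) {
  tr <- as.data.table(track)
  val <- tr[[ncol(tr)]]
  gr <- GenomicRanges::GRanges(tr$chrom,
                               IRanges::IRanges(start = tr$start + 1L, end = tr$end),
                               score = as.numeric(val))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Single-c and w50 table input/output
#'
#' The per-cytosine ("single-c") TSV uses 1-based positions on output
#' (matching the deposited file style) and is converted back to the internal
#' 0-based convention on read; the window ("w50") TSV keeps 0-based window
#' starts.
#'
#' @param calls a [call_single_c()] table.
#' @param path file path.
#' @name io-tables
NULL

#' @rdname io-tables
#' @export
write_single_c <- function(calls, path) {
  out <- as.data.table(calls)
  out <- out[, .(chrom, pos = pos + 1L, strand, context, subcontext,
                 retained, converted, level)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname io-tables
#' @export
read_single_c <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  x[, pos := pos - 1L]
  setattr(x, "class", c("single_c", class(x)))
  x[]
}

#' @rdname io-tables
#' @param windows a [window_methylation()] table.
#' @param window,step tiling parameters recorded when reading back.
#' @export
write_w50 <- function(windows, path) {
  data.table::fwrite(as.data.table(windows), path, sep = "\t")
  invisible(path)
}

#' @rdname io-tables
#' @export
read_w50 <- function(path, window = 50L, step = window) {
  x <- data.table::fread(path, sep = "\t")
  setattr(x, "window", as.integer(window))
  setattr(x, "step", as.integer(step))
  setattr(x, "class", c("window_table", class(x)))
  x[]
}
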