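#' Cytosine sequence contexts
#'
#' Every cytosine is classified by its two downstream bases on its own
#' strand: CG (next base G), CHG (next base H, then G) or CHH (both H),
#' with H = A, C or T. The three classes are mutually exclusive and jointly
#' exhaustive over context-defined cytosines. Subcontext tokens refine the
#' classes: for CG sites the NCG triplet given by the 5' neighbour (ACG,
#' CCG, GCG, TCG) plus the token `DCG` when that neighbour is not C
#' (D = A, G or T); for CHG sites `CWG` (W = A or T) or `CCG`; for CHH sites
#' `CWH`, plus `CWA` when the third base is A. Cytosines whose required
#' neighbours run off the chromosome or contain N are `undefined` and
#' excluded from all downstream analyses.
#'
#' Minus-strand cytosines appear as G on the forward reference; their context
#' is read toward decreasing coordinates through the complement.
#'
#' @param genome named character vector of chromosome sequences (A/C/G/T/N).
#' @return `cytosine_contexts()`: a `data.table` with one row per genomic
#'   cytosine on either strand: `chrom`, `pos` (0-based), `strand`,
#'   `context` (`CG`/`CHG`/`CHH`/`undefined`) and `subcontext`
#'   (comma-joined tokens, possibly empty).
#' @export
cytosine_contexts <- function(genome) {
  genome <- as_genome_seqs(genome)
  out <- lapply(names(genome), function(cn) {
    b <- strsplit(genome[[cn]], "", fixed = TRUE)[[1]]
    n <- length(b)
    plus <- which(b == "C")
    minus <- which(b == "G")
    res <- list()
    if (length(plus)) {
      b1 <- safe_base(b, plus + 1L)
      b2 <- safe_base(b, plus + 2L)
      b5 <- safe_base(b, plus - 1L)
      cls <- classify_context(b1, b2)
      res[[1L]] <- data.table(chrom = cn, pos = plus - 1L, strand = "+",
                              context = cls,
                              subcontext = subcontext_tokens(cls, b1, b2, b5))
    }
    if (length(minus)) {
      b1 <- comp_base(safe_base(b, minus - 1L))
      b2 <- comp_base(safe_base(b, minus - 2L))
      b5 <- comp_base(safe_base(b, minus + 1L))
      cls <- classify_context(b1, b2)
      res[[2L]] <- data.table(chrom = cn, pos = minus - 1L, strand = "-",
                              context = cls,
                              subcontext = subcontext_tokens(cls, b1, b2, b5))
    }
    rbindlist(res)
  })
  out <- rbindlist(out)
  setorder(out, chrom, pos, strand)
  out[]
}

# next-base classification shared by both strands; b1/b2 are the first and
# second downstream bases on the cytosine's own strand ("" = off-chromosome)
classify_context <- function(b1, b2) {
  H <- c("A", "C", "T")
  ctx <- rep("undefined", length(b1))
  ctx[b1 == "G"] <- "CG"
  chg <- b1 %in% H & b2 == "G"
  chh <- b1 %in% H & b2 %in% H
  ctx[chg] <- "CHG"
  ctx[chh] <- "CHH"
  ctx
}

subcontext_tokens <- function(ctx, b1, b2, b5) {
  sub <- character(length(ctx))
  W <- c("A", "T")
  is_cg <- ctx == "CG"
  good5 <- b5 %in% c("A", "C", "G", "T")
  ncg <- is_cg & good5
  sub[ncg] <- paste0(b5[ncg], "CG")
  dcg <- ncg & b5 != "C"
  sub[dcg] <- paste0(sub[dcg], ",DCG")
  is_chg <- ctx == "CHG"
  sub[is_chg & b1 %in% W] <- "CWG"
  sub[is_chg & b1 == "C"] <- "CCG"
  is_chh <- ctx == "CHH"
  cwh <- is_chh & b1 %in% W
  sub[cwh] <- "CWH"
  cwa <- cwh & b2 == "A"
  sub[cwa] <- paste0(sub[cwa], ",CWA")
  sub
}

safe_base <- function(b, idx) {
  out <- rep("", length(idx))
  ok <- idx >= 1L & idx <= length(b)
  out[ok] <- b[idx[ok]]
  out
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Context of a single cytosine
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param pos 0-based position of the cytosine (a reference C for `strand
#'   "+"`, a reference G for `strand "-"`).
#' @param strand `"+"` or `"-"`.
#' @return list with elements `context` and `subcontext` (character vector of
#'   tokens, possibly empty).
#' @export
#' @examples
#' assign_context(c(chr = "TACGA"), "chr", 2, "+")  # CG, subcontext ACG/DCG
assign_context <- function(genome, chrom, pos, strand = "+") {
  genome <- as_genome_seqs(genome)
  b <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
  base <- b[pos + 1L]
  if (strand == "+") {
    if (!identical(base, "C")) stop("base at position is not a forward-strand C")
    b1 <- safe_base(b, pos + 2L); b2 <- safe_base(b, pos + 3L)
    b5 <- safe_base(b, pos)
  } else {
    if (!identical(base, "G")) stop("base at position is not a reverse-strand C")
    b1 <- comp_base(safe_base(b, pos)); b2 <- comp_base(safe_base(b, pos - 1L))
    b5 <- comp_base(safe_base(b, pos + 2L))
  }
  ctx <- classify_context(b1, b2)
  sub <- subcontext_tokens(ctx, b1, b2, b5)
  list(context = ctx,
       subcontext = if (nzchar(sub)) strsplit(sub, ",", fixed = TRUE)[[1]] else character())
}

# accept a named character vector, a list, or a sim_genome object
as_genome_seqs <- function(genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$seq
  if (is.list(genome)) genome <- unlist(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named by chromosome")
  toupper(genome)
}
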