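#' Per-cytosine methylation calls ("single-c" table)
#'
#' Joins a pileup with the reference context table and computes the
#' methylation level of every covered, context-defined cytosine as
#' retained / (retained + converted). Cytosines with `undefined` context
#' (N in the context window or chromosome edge) are excluded; cytosines with
#' zero coverage are absent by construction.
#'
#' @param pile output of [pileup()].
#' @param genome named character vector of chromosome sequences or
#'   `sim_genome`.
#' @return a `data.table` of class `single_c`, sorted by chromosome then
#'   position: `chrom`, `pos` (0-based), `strand`, `context`, `subcontext`,
#'   `retained`, `converted`, `level`.
#' @export
call_single_c <- function(pile, genome) {
  ctab <- cytosine_contexts(genome)
  calls <- merge(as.data.table(pile), ctab, by = c("chrom", "pos", "strand"),
                 all.x = TRUE, sort = FALSE)
  if (anyNA(calls$context))
    stop("pileup references positions that are not reference cytosines")
  calls <- calls[context != "undefined"]
  calls[, level := retained / (retained + converted)]
  setorder(calls, chrom, pos, strand)
  setcolorder(calls, c("chrom", "pos", "strand", "context", "subcontext",
                       "retained", "converted", "level"))
  setattr(calls, "class", c("single_c", class(calls)))
  calls[]
}

#' Genome-wide average methylation of a context
#'
#' Unweighted mean of per-cytosine levels over cytosines of one context,
#' optionally restricted to a chromosome compartment and a minimum coverage.
#' When a non-conversion background `b` (apparent methylation of fully
#' unmethylated cytosines, estimated e.g. from the organelle compartment via
#' [estimate_nonconversion()]) is supplied, levels are corrected as
#' `(level - b) / (1 - b)` before averaging; the corrected values are not
#' clipped at zero so the mean stays unbiased.
#'
#' @param calls a [call_single_c()] table.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param chroms optional chromosome names to restrict to (e.g. the nuclear
#'   compartment).
#' @param min_coverage minimum retained + converted count (default 1: every
#'   covered cytosine counts).
#' @param nonconversion non-conversion background to correct for (default 0:
#'   raw levels).
#' @return the mean level, or `NA_real_` (with a warning) when no cytosine
#'   passes the filters.
#' @export
genome_average <- function(calls, context, chroms = NULL, min_coverage = 1L,
                           nonconversion = 0) {
  cx <- context
  sel <- calls$context == cx & (calls$retained + calls$converted) >= min_coverage
  if (!is.null(chroms)) sel <- sel & calls$chrom %in% chroms
  if (!any(sel)) {
    warning("no cytosines pass the filters; average undefined")
    return(NA_real_)
  }
  lv <- calls$level[sel]
  if (nonconversion > 0) lv <- (lv - nonconversion) / (1 - nonconversion)
  mean(lv)
}

#' Average methylation inside annotated features
#'
#' [genome_average()] restricted to cytosines falling inside features of one
#' type (TE-level averages for the knockout loss figures).
#'
#' @inheritParams genome_average
#' @param features annotation `data.frame` with 0-based half-open `chrom`,
#'   `start`, `end`, `type` (a `sim_genome$features` table works directly).
#' @param type feature type to keep (default `"TE"`).
#' @return mean level over cytosines inside the features, or `NA_real_`.
#' @export
feature_average <- function(calls, features, type = "TE", context,
                            min_coverage = 1L, nonconversion = 0) {
  f <- as.data.table(features)
  if ("type" %in% names(f)) f <- f[f$type == type, ]
  inside <- overlaps_feature(calls, f)
  genome_average(calls[inside], context, min_coverage = min_coverage,
                 nonconversion = nonconversion)
}

# logical: does each call position fall inside any feature interval
overlaps_feature <- function(calls, f) {
  if (nrow(f) == 0L) return(rep(FALSE, nrow(calls)))
  q <- GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(start = calls$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(f$chrom,
                              IRanges::IRanges(start = f$start + 1L, end = f$end))
  IRanges::overlapsAny(q, s)
}

#' Estimate the bisulfite non-conversion background
#'
#' Mean apparent methylation level over cytosines of chromosomes known to be
#' unmethylated (the organelle compartment in plant WGBS practice). This is
#' an estimate of `1 - conversion_rate`, usable as the `nonconversion`
#' argument of [genome_average()].
#'
#' @param calls a [call_single_c()] table.
#' @param chroms control chromosome names (default `"chrC"`).
#' @return estimated background fraction.
#' @export
estimate_nonconversion <- function(calls, chroms = "chrC") {
  sel <- calls$chrom %in% chroms
  if (!any(sel)) stop("no calls on the control chromosomes: ",
                      paste(chroms, collapse = ", "))
  # count-weighted so low-coverage cytosines do not dominate
  sum(calls$retained[sel]) / sum(calls$retained[sel] + calls$converted[sel])
}
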