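#' TE metaplot: methylation profile along elements aligned at the 5' end
#'
#' All TEs are aligned at their 5' end (strand-aware) and the unweighted
#' mean of per-cytosine levels is pooled within consecutive intervals
#' measured into the element; `flank` extends the profile upstream of the
#' alignment point (negative offsets). Per-interval contributing-TE counts
#' are reported, since intervals far from the alignment point are populated
#' by long elements only.
#'
#' @param calls a [call_single_c()] table.
#' @param tes stranded TE annotation (`chrom`, `start`, `end`, `strand`,
#'   0-based half-open).
#' @param context optional single context.
#' @param interval interval width in bp (default 100).
#' @param flank upstream flank in bp (default 0).
#' @return a `data.table`: `offset` (interval start, bp from the 5' end,
#'   negative = upstream), `mean_level`, `n_cytosines`, `n_tes`. Zero rows
#'   when `tes` is empty.
#' @export
te_metaplot <- function(calls, tes, context = NULL, interval = 100L,
                        flank = 0L) {
  tes <- as.data.table(tes)
  if ("type" %in% names(tes)) tes <- tes[tes$type == "TE", ]
  if (nrow(tes) == 0L)
    return(data.table(offset = integer(), mean_level = numeric(),
                      n_cytosines = integer(), n_tes = integer()))
  if (!"id" %in% names(tes)) tes$id <- sprintf("TE_%04d", seq_len(nrow(tes)))
  dt <- as.data.table(calls)
  if (!is.null(context)) {
    cx <- context
    dt <- dt[dt$context == cx, ]
  }
  q <- GenomicRanges::GRanges(dt$chrom,
                              IRanges::IRanges(start = dt$pos + 1L, width = 1L))
  s <- GenomicRanges::GRanges(tes$chrom,
                              IRanges::IRanges(start = tes$start + 1L - ifelse(tes$strand == "+", flank, 0L),
                                               end = tes$end + ifelse(tes$strand == "+", 0L, flank)))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (length(hits) == 0L)
    return(data.table(offset = integer(), mean_level = numeric(),
                      n_cytosines = integer(), n_tes = integer()))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  off <- ifelse(tes$strand[si] == "+",
                dt$pos[qi] - tes$start[si],
                (tes$end[si] - 1L) - dt$pos[qi])
  d <- data.table(offset = (floor(off / interval)) * as.integer(interval),
                  level = dt$level[qi], te = tes$id[si])
  out <- d[, .(mean_level = mean(level), n_cytosines = .N,
               n_tes = data.table::uniqueN(te)), by = offset]
  setorder(out, offset)
  out[]
}

#' Frequency of TE edges upstream of gene TSS
#'
#' For every gene the nearest facing TE edge is sought within `upstream` bp
#' of the transcription start site, in `window`-bp bins: genes on the plus
#' strand are tested against TE END positions, genes on the minus strand
#' against TE START positions (the edge nearest the gene), and only the
#' closest edge of any TE counts, so each gene contributes to at most one
#' bin. The result is the percentage of genes with a TE edge per bin.
#'
#' @param genes stranded gene annotation (`chrom`, `start`, `end`,
#'   `strand`, 0-based half-open); the TSS is `start` for `+` genes and
#'   `end - 1` for `-` genes.
#' @param tes TE annotation (strand not needed).
#' @param window bin width in bp (default 25).
#' @param upstream maximum distance upstream of the TSS (default 500).
#' @return a `data.table`: `offset` (bin start distance upstream, 0, 25,
#'   ...), `n_genes` (with their closest edge in the bin), `percent` (of all
#'   genes supplied).
#' @export
te_tss_histogram <- function(genes, tes, window = 25L, upstream = 500L) {
  genes <- as.data.table(genes)
  if ("type" %in% names(genes)) genes <- genes[genes$type == "gene", ]
  tes <- as.data.table(tes)
  if ("type" %in% names(tes)) tes <- tes[tes$type == "TE", ]
  if (nrow(genes) == 0L) stop("no genes supplied")
  if (!all(genes$strand %in% c("+", "-"))) stop("genes must be stranded")
  n_bins <- as.integer(ceiling(upstream / window))
  offsets <- (seq_len(n_bins) - 1L) * as.integer(window)
  dist <- rep(NA_integer_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    on_chrom <- tes[tes$chrom == genes$chrom[i], ]
    if (nrow(on_chrom) == 0L) next
    if (genes$strand[i] == "+") {
      tss <- genes$start[i]
      edge <- on_chrom$end - 1L      # last base of each TE
      d <- tss - edge                 # bp upstream, 1 = adjacent
    } else {
      tss <- genes$end[i] - 1L
      edge <- on_chrom$start          # first base of each TE
      d <- edge - tss
    }
    d <- d[d >= 1L & d <= upstream]
    if (length(d)) dist[i] <- min(d)
  }
  bin <- ifelse(is.na(dist), NA_integer_, (dist - 1L) %/% window)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  data.table(offset = offsets, n_genes = counts,
             percent = 100 * counts / nrow(genes))
}

#' Centile scheme for chromatin stratification
#'
#' Describes how a feature track is cut into quantile groups: 5 centiles
#' for GC fraction and TE size, 10 for siRNA counts, 4 for histone log2
#' ratios over H3 — the latter with the extra `ND` category for windows
#' lacking signal in any of H3K9me2, H3K4me3 or H3.
#'
#' @param feature feature name (free text, e.g. `"H3K9me2"`).
#' @param n_centiles number of quantile groups.
#' @param histone if `TRUE`, values are log2((mark + eps)/(H3 + eps)) and
#'   the ND rule applies.
#' @param eps pseudocount for histone ratios.
#' @return an object of class `centile_scheme`.
#' @export
centile_scheme <- function(feature, n_centiles = 5L, histone = FALSE,
                           eps = 0.01) {
  stopifnot(n_centiles >= 2L)
  structure(list(feature = feature, n_centiles = as.integer(n_centiles),
                 histone = histone, eps = eps),
            class = "centile_scheme")
}

#' Stratify per-window percent change over feature centiles
#'
#' Assigns each window to an empirical quantile group of a feature track
#' (ties resolved to the lower centile) and summarises the percent-change
#' distribution per group as box-plot statistics (median, quartiles,
#' 1.5 x IQR whiskers). For histone schemes the feature is
#' log2((mark + eps)/(H3 + eps)) and windows with no signal in any of mark,
#' the opposing mark, or H3 fall in the `ND` group; supply those tracks via
#' `nd_tracks`.
#'
#' @param values numeric per-window values to stratify (e.g. percent
#'   change), already filtered to the analysis windows.
#' @param feature numeric feature track aligned with `values` (for histone
#'   schemes, the raw mark signal).
#' @param scheme a [centile_scheme()].
#' @param h3 total-H3 track (histone schemes only).
#' @param nd_tracks optional list of tracks whose zero/NA entries force a
#'   window into the `ND` group (histone schemes; typically list(H3K9me2,
#'   H3K4me3, H3)).
#' @return list of class `centile_strata`: `assignment` (`group` per
#'   window, `"ND"` or `"Q1"..`), `summary` (per group: n, median, q1, q3,
#'   whiskers), `feature_value` (the stratified feature).
#' @export
stratify_quantiles <- function(values, feature, scheme, h3 = NULL,
                               nd_tracks = NULL) {
  if (length(values) != length(feature))
    stop("values and feature track must align window-for-window")
  fv <- feature
  nd <- rep(FALSE, length(values))
  if (scheme$histone) {
    if (is.null(h3)) stop("histone scheme requires the total-H3 track")
    if (length(h3) != length(values)) stop("H3 track must align with values")
    fv <- log2((feature + scheme$eps) / (h3 + scheme$eps))
    nd_tracks <- if (is.null(nd_tracks)) list(feature, h3) else nd_tracks
    for (tr in nd_tracks) nd <- nd | is.na(tr) | tr == 0
  }
  nd <- nd | is.na(fv)
  group <- rep(NA_character_, length(values))
  group[nd] <- "ND"
  if (any(!nd)) {
    f <- fv[!nd]
    breaks <- unique(quantile(f, probs = seq_len(scheme$n_centiles - 1L) /
                                scheme$n_centiles, names = FALSE))
    # (t_i, t_{i+1}] intervals: a value equal to a boundary goes to the
    # lower centile
    g <- findInterval(f, breaks, left.open = TRUE) + 1L
    group[!nd] <- paste0("Q", g)
  }
  lvls <- c(paste0("Q", seq_len(scheme$n_centiles)), if (any(nd)) "ND")
  smry <- rbindlist(lapply(lvls, function(gr) {
    v <- values[group == gr & !is.na(group)]
    if (length(v) == 0L)
      return(data.table(group = gr, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_,
                        lower_whisker = NA_real_, upper_whisker = NA_real_))
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    iqr <- qs[3] - qs[1]
    data.table(group = gr, n = length(v), median = qs[2], q1 = qs[1],
               q3 = qs[3],
               lower_whisker = min(v[v >= qs[1] - 1.5 * iqr]),
               upper_whisker = max(v[v <= qs[3] + 1.5 * iqr]))
  }))
  structure(list(assignment = data.table(group = group, value = values,
                                         feature_value = fv),
                 summary = smry, scheme = scheme),
            class = "centile_strata")
}

#' Pairwise Pearson correlation matrix of window-level tracks
#'
#' Pearson correlations between columns over pairwise-complete windows;
#' entries with fewer than 3 complete pairs or a zero-variance member are
#' `NA` (flagged with a warning).
#'
#' @param x data.frame/matrix of aligned window-level columns (methylation
#'   fractions per context, GC, histone marks, ...).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two tracks")
  suppressWarnings(r <- cor(m, use = "pairwise.complete.obs"))
  # enforce NA where <3 complete pairs
  for (i in seq_len(ncol(m))) for (j in seq_len(ncol(m))) {
    if (sum(stats::complete.cases(m[, c(i, j)])) < 3L) r[i, j] <- NA_real_
  }
  diag(r) <- ifelse(apply(m, 2, function(v) sum(!is.na(v))) >= 1L, 1, NA_real_)
  if (anyNA(r)) warning("undefined correlation entries (zero variance or <3 complete pairs)")
  r
}

#' Overlap between siRNA, methylation and TE annotation
#'
#' Classifies every TE as methylated (mean level of the chosen context's
#' cytosines inside the TE at or above `meth_min_level`) and/or
#' siRNA-positive (summed siRNA counts over the TE's windows at or above
#' `sirna_min_count`), and reports the overlap. Both thresholds are
#' mandatory: no default is implied.
#'
#' @param sirna per-window siRNA track (`chrom`, `start`, `end`, `siRNA`),
#'   e.g. the simulator's `tracks`.
#' @param calls a [call_single_c()] table.
#' @param tes TE annotation.
#' @param context methylation context (default `"CHH"`).
#' @param meth_min_level minimum mean methylation level for a TE to count as
#'   methylated.
#' @param sirna_min_count minimum summed siRNA count for a TE to count as
#'   siRNA-overlapped.
#' @return list: `n_te`, `n_methylated`, `n_sirna`, `n_both`, `n_neither`,
#'   `percent_methylated_with_sirna`.
#' @export
overlap_summary <- function(sirna, calls, tes, context = "CHH",
                            meth_min_level, sirna_min_count) {
  if (missing(meth_min_level) || missing(sirna_min_count))
    stop("meth_min_level and sirna_min_count must be given explicitly")
  tes <- as.data.table(tes)
  if ("type" %in% names(tes)) tes <- tes[tes$type == "TE", ]
  if (nrow(tes) == 0L)
    return(list(n_te = 0L, n_methylated = 0L, n_sirna = 0L, n_both = 0L,
                n_neither = 0L, percent_methylated_with_sirna = NA_real_))
  if (!"id" %in% names(tes)) tes$id <- sprintf("TE_%04d", seq_len(nrow(tes)))
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1L, tes$end))
  cx <- context
  dt <- as.data.table(calls)
  dt <- dt[dt$context == cx, ]
  meth <- rep(FALSE, nrow(tes))
  if (nrow(dt)) {
    cg <- GenomicRanges::GRanges(dt$chrom,
                                 IRanges::IRanges(dt$pos + 1L, width = 1L))
    h <- GenomicRanges::findOverlaps(cg, te_gr)
    if (length(h)) {
      mlev <- tapply(dt$level[S4Vectors::queryHits(h)],
                     S4Vectors::subjectHits(h), mean)
      meth[as.integer(names(mlev))] <- mlev >= meth_min_level
    }
  }
  sirna <- as.data.table(sirna)
  spos <- rep(FALSE, nrow(tes))
  if (nrow(sirna)) {
    sg <- GenomicRanges::GRanges(sirna$chrom,
                                 IRanges::IRanges(sirna$start + 1L, sirna$end))
    h <- GenomicRanges::findOverlaps(sg, te_gr)
    if (length(h)) {
      ssum <- tapply(sirna$siRNA[S4Vectors::queryHits(h)],
                     S4Vectors::subjectHits(h), sum)
      spos[as.integer(names(ssum))] <- ssum >= sirna_min_count
    }
  }
  n_both <- sum(meth & spos)
  list(n_te = nrow(tes), n_methylated = sum(meth), n_sirna = sum(spos),
       n_both = n_both, n_neither = sum(!meth & !spos),
       percent_methylated_with_sirna =
         if (sum(meth)) 100 * n_both / sum(meth) else NA_real_)
}

#' Smoothed chromosome-scale methylation profile
#'
#' Unweighted mean level per fixed genomic bin along one chromosome,
#' followed by LOWESS (locally weighted linear) smoothing with the given
#' span. A chromosome shorter than one bin yields a single unsmoothed value.
#'
#' @param calls a [call_single_c()] table.
#' @param chrom chromosome to profile.
#' @param context optional context filter.
#' @param bin bin size in bp (default 100 kb).
#' @param span LOWESS span as a fraction of the bins (default 0.1).
#' @return a `data.table`: `mid` (bin midpoint), `mean_level`, `smooth`.
#' @export
chromosome_profile <- function(calls, chrom, context = NULL, bin = 100000L,
                               span = 0.1) {
  cn <- chrom
  dt <- as.data.table(calls)
  dt <- dt[dt$chrom == cn, ]
  if (!is.null(context)) {
    cx <- context
    dt <- dt[dt$context == cx, ]
  }
  if (nrow(dt) == 0L) stop("no calls on chromosome ", cn)
  binsz <- as.integer(bin)
  dt[, bin := (pos %/% binsz) * binsz]
  prof <- dt[, .(mean_level = mean(level)), by = bin]
  setorder(prof, bin)
  out <- data.table(mid = prof$bin + binsz / 2,
                    mean_level = prof$mean_level)
  if (nrow(out) < 2L) {
    out$smooth <- out$mean_level
  } else {
    sm <- lowess(out$mid, out$mean_level, f = span)
    out$smooth <- sm$y[match(out$mid, sm$x)]
  }
  out
}
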