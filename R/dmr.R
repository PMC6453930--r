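#' Call differentially methylated 50-bp windows
#'
#' Compares two [window_methylation()] tables on the same tiling. A window
#' is tested when its fraction reaches `min_fraction` in EITHER sample and
#' it has at least `min_informative` informative sequenced cytosines in
#' BOTH. Each tested window gets a two-sided Fisher's exact test on the
#' 2x2 table \[retained, converted\] x \[WT, mutant\]; windows with
#' `p < alpha` are reported as DMRs with the percent-change statistic and a
#' direction: `hypo` when the mutant fraction is below wild type, `hyper`
#' otherwise. No multiple-testing correction is applied by default
#' (`p_adjust = "BH"` enables Benjamini-Hochberg).
#'
#' @param wt,mut `window_table`s for wild type and mutant (same window size,
#'   step, and context layout).
#' @param context optional single context to restrict to.
#' @param min_fraction minimum fractional methylation in either sample
#'   (default 0.1).
#' @param min_informative minimum informative cytosines in both samples
#'   (default 10).
#' @param alpha p-value threshold (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return an object of class `dmr_result`: list with `tested` (all tested
#'   windows with fractions, `percent_change`, `p`), `dmrs` (the subset with
#'   `p < alpha`, plus `direction`), and counts `n_tested`, `n_hypo`,
#'   `n_hyper`.
#' @export
call_dmrs <- function(wt, mut, context = NULL, min_fraction = 0.1,
                      min_informative = 10L, alpha = 0.05,
                      p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!identical(attr(wt, "window"), attr(mut, "window")) ||
      !identical(attr(wt, "step"), attr(mut, "step")))
    stop("window tables use mismatched tilings")
  a <- as.data.table(wt); b <- as.data.table(mut)
  if (!is.null(context)) {
    cx <- context
    a <- a[a$context == cx, ]; b <- b[b$context == cx, ]
  }
  m <- merge(a, b, by = c("chrom", "start", "context"),
             suffixes = c("_wt", "_mut"))
  m <- m[(m$fraction_wt >= min_fraction | m$fraction_mut >= min_fraction) &
           m$n_informative_wt >= min_informative &
           m$n_informative_mut >= min_informative, ]
  if (nrow(m) == 0L) {
    tested <- m
    tested$percent_change <- numeric()
    tested$p <- numeric()
  } else {
    tested <- m
    tested$percent_change <-
      percent_methylation_change(m$fraction_wt, m$fraction_mut)
    tested$p <- mapply(function(rw, cw, rm, cm)
      fisher.test(matrix(c(rw, cw, rm, cm), nrow = 2))$p.value,
      m$retained_wt, m$converted_wt, m$retained_mut, m$converted_mut)
    if (p_adjust == "BH") tested$p <- stats::p.adjust(tested$p, "BH")
  }
  dmrs <- tested[tested$p < alpha, ]
  dmrs$direction <- ifelse(dmrs$fraction_mut < dmrs$fraction_wt,
                           "hypo", "hyper")
  structure(list(tested = tested, dmrs = dmrs,
                 n_tested = nrow(tested),
                 n_hypo = sum(dmrs$direction == "hypo"),
                 n_hyper = sum(dmrs$direction == "hyper"),
                 alpha = alpha),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("dmr_result:", x$n_tested, "windows tested,",
      nrow(x$dmrs), "DMRs at p <", x$alpha,
      "(", x$n_hypo, "hypo /", x$n_hyper, "hyper )\n")
  invisible(x)
}
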