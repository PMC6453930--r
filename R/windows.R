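#' Windowed fractional methylation ("w50" table)
#'
#' Pools per-cytosine counts of one or all contexts into fixed genomic
#' windows (50-bp tiles by default; an optional `step < window` produces
#' overlapping sliding windows). The window fraction is computed from pooled
#' counts — retained / (retained + converted) — i.e. count-weighted, not a
#' mean of per-cytosine levels. `n_informative` is the total number of
#' sequenced C/T observations at context cytosines in the window. Windows
#' with no informative observation are absent.
#'
#' @param calls a [call_single_c()] table.
#' @param window window size in bp (> 0).
#' @param step tile step (default `window`: non-overlapping tiles). Must
#'   divide `window` when smaller.
#' @param context optional single context to restrict to; default keeps all
#'   three, one row per (window, context).
#' @return a `data.table` of class `window_table`: `chrom`, `start`
#'   (0-based, multiple of `step`), `context`, `retained`, `converted`,
#'   `n_informative`, `fraction`; attributes `window` and `step`.
#' @export
window_methylation <- function(calls, window = 50L, step = window,
                               context = NULL) {
  if (window <= 0L) stop("window size must be > 0")
  if (step <= 0L || step > window || window %% step != 0L)
    stop("step must be a positive divisor of the window size")
  dt <- as.data.table(calls)
  if (!is.null(context)) {
    cx <- context
    dt <- dt[dt$context == cx, ]
  }
  n_shift <- window %/% step
  pieces <- lapply(seq_len(n_shift) - 1L, function(i) {
    d <- data.table::copy(dt)
    d[, win := ((pos - i * step) %/% window) * window + i * step]
    d[win >= 0L]
  })
  dt <- rbindlist(pieces)
  out <- dt[, .(retained = sum(retained), converted = sum(converted)),
            by = .(chrom, start = win, context)]
  out[, n_informative := retained + converted]
  out[, fraction := retained / n_informative]
  out <- out[n_informative > 0L]
  setorder(out, chrom, start, context)
  setattr(out, "window", as.integer(window))
  setattr(out, "step", as.integer(step))
  setattr(out, "class", c("window_table", class(out)))
  out[]
}

#' Percent methylation change between two samples
#'
#' The asymmetric difference statistic used for all mutant-vs-wild-type
#' comparisons: the difference in methylation divided by the level of the
#' sample with the HIGHER methylation, signed so that loss in the second
#' sample is positive,
#' \deqn{+100 (a - b)/a \ \mathrm{if}\ a > b; \quad -100 (b - a)/b \ \mathrm{if}\ a < b; \quad 0 \ \mathrm{if}\ a = b.}
#' Bounded in \[-100, 100\] and antisymmetric in its arguments; two zero
#' fractions fall in the equality branch and give 0.
#'
#' @param wt,mut methylation fractions in \[0, 1\] (vectorized).
#' @return percent change in \[-100, 100\].
#' @export
#' @examples
#' percent_methylation_change(0.5, 0.25)  # +50
#' percent_methylation_change(0.2, 0.5)   # -60
percent_methylation_change <- function(wt, mut) {
  if (any(c(wt, mut) < 0 | c(wt, mut) > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  n <- max(length(wt), length(mut))
  wt <- rep_len(wt, n)
  mut <- rep_len(mut, n)
  out <- numeric(n)
  hi <- wt > mut
  lo <- wt < mut
  out[hi] <- (wt[hi] - mut[hi]) / wt[hi] * 100
  out[lo] <- -(mut[lo] - wt[lo]) / mut[lo] * 100
  out[is.na(wt) | is.na(mut)] <- NA_real_
  out
}
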