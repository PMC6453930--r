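#' Score bisulfite Sanger clones against an amplicon reference
#'
#' For amplicon bisulfite sequencing (forward strand only): clones are
#' sequenced plasmid inserts aligned end-to-end to the untreated reference.
#' At every reference forward-strand cytosine, a clone base C scores
#' methylated (1), T unmethylated (0), anything else missing (NA). Clones
#' with more than 10% non-C/T bases at cytosine sites are rejected with a
#' warning. Site contexts are read off the reference.
#'
#' @param reference amplicon reference sequence (untreated, forward strand).
#' @param clones character vector of clone sequences, same length as the
#'   reference; names become clone identifiers.
#' @return an object of class `clone_matrix`: list with `matrix` (sites x
#'   clones, 0/1/NA) and `sites` (`pos` 0-based, `context`, `subcontext`,
#'   `fraction` = methylated clones / scored clones).
#' @export
clone_methylation_matrix <- function(reference, clones) {
  reference <- toupper(reference)
  clones <- toupper(clones)
  if (is.null(names(clones)) || any(!nzchar(names(clones))))
    names(clones) <- sprintf("clone_%02d", seq_along(clones))
  if (any(nchar(clones) != nchar(reference)))
    stop("clones must align end-to-end to the reference (equal length)")
  rb <- strsplit(reference, "", fixed = TRUE)[[1]]
  sites <- which(rb == "C")
  if (length(sites) == 0L) stop("reference contains no cytosines")

  score_one <- function(seq) {
    b <- strsplit(seq, "", fixed = TRUE)[[1]][sites]
    s <- rep(NA_real_, length(sites))
    s[b == "C"] <- 1
    s[b == "T"] <- 0
    s
  }
  m <- vapply(clones, score_one, numeric(length(sites)))
  m <- matrix(m, nrow = length(sites), dimnames = list(NULL, names(clones)))
  bad <- colMeans(is.na(m)) > 0.1
  if (any(bad)) {
    warning("rejecting clone(s) with >10% non-C/T at cytosine sites: ",
            paste(names(clones)[bad], collapse = ", "))
    m <- m[, !bad, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("no clones passed quality filtering")

  ctab <- cytosine_contexts(c(amplicon = reference))
  ctab <- ctab[ctab$strand == "+", ]
  idx <- match(sites - 1L, ctab$pos)
  sites_dt <- data.table(pos = sites - 1L,
                         context = ctab$context[idx],
                         subcontext = ctab$subcontext[idx],
                         fraction = rowMeans(m, na.rm = TRUE))
  structure(list(matrix = m, sites = sites_dt), class = "clone_matrix")
}

#' Paired t-test on per-site methylation fractions
#'
#' Classical paired t on the per-site differences between two genotypes'
#' site-fraction vectors (sites paired by position), with explicit handling
#' of the degenerate cases the textbook statistic leaves undefined: when all
#' differences are zero the test is reported as t = 0, p = 1; when the
#' differences are constant and nonzero, t is infinite and p = 0, flagged
#' `degenerate`.
#'
#' @param a,b numeric vectors of per-site fractions, paired by position; or
#'   `clone_matrix` objects (their site fractions are used, paired on site
#'   position).
#' @param context optional context filter (requires `clone_matrix` inputs or
#'   a `contexts` vector).
#' @param contexts optional character vector of per-site contexts matching
#'   `a`/`b` when they are plain numeric vectors.
#' @return list of class `paired_t`: `t`, `df`, `p` (two-sided), `n`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b, context = NULL, contexts = NULL) {
  if (inherits(a, "clone_matrix")) {
    if (!inherits(b, "clone_matrix")) stop("both inputs must be clone matrices")
    m <- merge(a$sites[, c("pos", "context", "fraction")],
               b$sites[, c("pos", "context", "fraction")],
               by = c("pos", "context"))
    if (!is.null(context)) {
      cx <- context
      m <- m[m$context == cx, ]
    }
    a <- m$fraction.x; b <- m$fraction.y
  } else if (!is.null(context)) {
    if (is.null(contexts)) stop("context filtering needs per-site contexts")
    keep <- contexts == context
    a <- a[keep]; b <- b[keep]
  }
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired sites with defined values")
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0)
      return(structure(list(t = 0, df = n - 1L, p = 1, n = n, mean_diff = 0,
                            degenerate = TRUE), class = "paired_t"))
    return(structure(list(t = sign(md) * Inf, df = n - 1L, p = 0, n = n,
                          mean_diff = md, degenerate = TRUE),
                     class = "paired_t"))
  }
  t <- md / (s / sqrt(n))
  structure(list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1L), n = n,
                 mean_diff = md, degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat("paired t:", signif(x$t, 4), "on", x$df, "df, two-sided p =",
      format.pval(x$p), "( n =", x$n, ")\n")
  invisible(x)
}
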