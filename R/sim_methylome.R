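#' Simulate a ground-truth methylome
#'
#' Builds a per-cytosine record of true methylation probabilities
#' (`p_true`), the ground truth used by the read simulator and by recovery
#' tests. The landscape is TE-restricted: cytosines outside TEs (and the
#' organelle control chromosome) have `p_true = 0`. Inside TEs, `p_true` is a
#' logistic function of the standardized local H3K9me2 and window GC signals,
#' with the per-context intercept calibrated by root-finding so the mean over
#' TE cytosines of each context equals `base_levels` exactly in expectation.
#' A [genotype_effect()] then scales the wild-type probabilities
#' multiplicatively per context (with optional subcontext overrides and CHH
#' chromatin redistribution).
#'
#' @param genome a [simulate_genome()] result.
#' @param effect optional [genotype_effect()]; `NULL` or the identity preset
#'   returns the wild-type methylome.
#' @param base_levels named fractions: wild-type mean `p_true` per context
#'   over TE cytosines; names must be exactly `CG`, `CHG`, `CHH`.
#' @return a `data.table` of class `methylome_model` with columns `chrom`,
#'   `pos` (0-based), `strand`, `context`, `subcontext`, `p` (true
#'   methylation probability) and `het` (standardized local H3K9me2 used by
#'   redistribution effects). One row per context-defined genomic cytosine.
#' @export
simulate_methylome <- function(genome, effect = NULL,
                               base_levels = c(CG = 0.8, CHG = 0.7, CHH = 0.2)) {
  stopifnot(inherits(genome, "sim_genome"))
  if (!setequal(names(base_levels), c("CG", "CHG", "CHH")))
    stop("base_levels must be named CG, CHG, CHH (unknown or missing context key)")
  if (any(base_levels <= 0 | base_levels >= 1))
    stop("base_levels must lie in (0, 1)")

  ctab <- cytosine_contexts(genome$seq)
  ctab <- ctab[context != "undefined"]

  # window-level covariates mapped to cytosines
  ctab[, win := (pos %/% 50L) * 50L]
  tr <- genome$tracks[, .(chrom, win = start, H3K9me2, GC)]
  ctab <- merge(ctab, tr, by = c("chrom", "win"), all.x = TRUE, sort = FALSE)
  # TE membership is per cytosine (windows only supply the covariates)
  in_te <- overlaps_feature(ctab,
                            genome$features[genome$features$type == "TE", ])

  k9 <- log1p(ctab$H3K9me2)
  if (any(in_te) && sd(k9[in_te]) > 0) {
    z_k9 <- (k9 - mean(k9[in_te])) / sd(k9[in_te])
  } else z_k9 <- rep(0, nrow(ctab))
  if (any(in_te) && sd(ctab$GC[in_te]) > 0) {
    z_gc <- (ctab$GC - mean(ctab$GC[in_te])) / sd(ctab$GC[in_te])
  } else z_gc <- rep(0, nrow(ctab))
  x <- z_k9 + 0.5 * z_gc

  p <- numeric(nrow(ctab))
  for (cx in c("CG", "CHG", "CHH")) {
    sel <- in_te & ctab$context == cx
    if (!any(sel)) next
    a <- calibrate_intercept(x[sel], base_levels[[cx]])
    p[sel] <- plogis(a + x[sel])
  }

  model <- ctab[, .(chrom, pos, strand, context, subcontext)]
  model[, p := p]
  model[, het := z_k9]
  setorder(model, chrom, pos, strand)
  setattr(model, "base_levels", base_levels)
  setattr(model, "effect", "identity")
  setattr(model, "class", c("methylome_model", class(model)))
  if (!is.null(effect)) model <- apply_genotype_effect(model, effect)
  model[]
}

# solve mean(plogis(a + x)) = target for the intercept a (monotone in a)
calibrate_intercept <- function(x, target) {
  uniroot(function(a) mean(plogis(a + x)) - target,
          lower = -30, upper = 30, tol = 1e-10)$root
}

#' Apply a genotype effect to a methylome model
#'
#' Mutant `p_true` is the wild-type value times the effect's per-context
#' retention factor; subcontext overrides replace the context factor where
#' their token matches; a positive CHH redistribution coefficient `d` then
#' rescales CHH by `exp(-d * het)` capped at 1, depleting heterochromatic and
#' inflating euchromatic CHH. The identity effect returns the model
#' unchanged.
#'
#' @param model a `methylome_model`.
#' @param effect a [genotype_effect()].
#' @return a new `methylome_model` with updated `p`.
#' @export
apply_genotype_effect <- function(model, effect) {
  stopifnot(inherits(model, "methylome_model"), inherits(effect, "genotype_effect"))
  out <- data.table::copy(model)
  r <- effect$retention[out$context]
  for (tok in names(effect$subcontext_retention)) {
    hit <- grepl(paste0("(^|,)", tok, "(,|$)"), out$subcontext)
    r[hit] <- effect$subcontext_retention[[tok]]
  }
  out[, p := p * r]
  if (effect$chh_redistribution > 0) {
    d <- effect$chh_redistribution
    out[context == "CHH", p := pmin(1, p * exp(-d * het))]
  }
  setattr(out, "effect", effect$name)
  out[]
}
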