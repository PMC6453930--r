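#' Simulation configuration
#'
#' Parameters of the synthetic genome / methylome / read generator. The
#' defaults describe the study conditions every downstream stage is validated
#' against: a small multi-chromosome nuclear genome in which transposable
#' elements (TEs) cover roughly half the sequence, an unmethylated
#' organelle-like control chromosome, 30x single-end coverage, and a
#' bisulfite conversion efficiency of 99.5%.
#'
#' @param n_chromosomes number of nuclear chromosomes.
#' @param chrom_length length of each nuclear chromosome (bp).
#' @param te_count total number of TEs placed across the nuclear genome.
#' @param te_size_range numeric pair, min/max TE length (bp); sizes are drawn
#'   log-uniformly. Minimum must be >= 50 and maximum <= `chrom_length / 4`.
#' @param gene_count total number of genes.
#' @param gene_size_range numeric pair, min/max gene length (bp).
#' @param gc_content baseline genomic GC fraction; TE neighbourhoods are
#'   shifted upward with TE size (long TEs sit in GC-richer, more
#'   heterochromatic sequence).
#' @param organelle_length length of the unmethylated organelle-like control
#'   chromosome `"chrC"` (0 disables it). Used to estimate the non-conversion
#'   background.
#' @param depth mean read depth per position.
#' @param read_length read length (bp), single-end.
#' @param conversion_rate probability an UNmethylated cytosine is converted
#'   and sequenced as T.
#' @param methylation_failure_rate probability a methylated cytosine is
#'   nevertheless read as T.
#' @param error_rate optional uniform substitution sequencing-error rate
#'   (default 0: reads differ from the genome only through bisulfite
#'   chemistry).
#' @param seed integer seed; an identical configuration (including seed)
#'   reproduces every output bit-identically.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000, te_count = 8)
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 100000,
                       te_count = 70,
                       te_size_range = c(100, 5000),
                       gene_count = 30,
                       gene_size_range = c(800, 2500),
                       gc_content = 0.34,
                       organelle_length = 20000,
                       depth = 30,
                       read_length = 75,
                       conversion_rate = 0.995,
                       methylation_failure_rate = 0.005,
                       error_rate = 0,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              te_count = as.integer(te_count),
              te_size_range = as.numeric(te_size_range),
              gene_count = as.integer(gene_count),
              gene_size_range = as.numeric(gene_size_range),
              gc_content = gc_content,
              organelle_length = as.integer(organelle_length),
              depth = depth,
              read_length = as.integer(read_length),
              conversion_rate = conversion_rate,
              methylation_failure_rate = methylation_failure_rate,
              error_rate = error_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length >= 1000,
            cfg$te_count >= 0, cfg$gene_count >= 0,
            length(cfg$te_size_range) == 2L,
            cfg$read_length >= 20)
  fracs <- c(gc_content = cfg$gc_content,
             conversion_rate = cfg$conversion_rate,
             methylation_failure_rate = cfg$methylation_failure_rate,
             error_rate = cfg$error_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("all rate/fraction parameters must lie in [0, 1]")
  if (cfg$te_count > 0) {
    if (cfg$te_size_range[1] < 50)
      stop("te_size_range minimum must be >= 50 bp")
    if (cfg$te_size_range[2] > cfg$chrom_length / 4)
      stop("te_size_range maximum must be <= chrom_length / 4")
  }
  invisible(cfg)
}

#' Genotype knockout effect on a methylome
#'
#' A multiplicative retention model for DNA-methyltransferase mutants:
#' the mutant's per-cytosine methylation probability is the wild-type
#' probability times a per-context retention factor, optionally overridden
#' for particular subcontexts, optionally redistributed along the
#' heterochromatin gradient for CHH.
#'
#' @param name label for the genotype.
#' @param r_cg,r_chg,r_chh retention factors in \[0, 1\] for the CG, CHG and
#'   CHH contexts (1 = unchanged, 0 = complete loss).
#' @param subcontext_retention optional named numeric vector of retention
#'   factors keyed by subcontext token (e.g. `c(DCG = 0.87)`); where a
#'   cytosine carries the token, the override replaces its context factor.
#' @param chh_redistribution nonnegative coefficient `d` of the CHH
#'   chromatin-redistribution term: mutant CHH probability is scaled by
#'   `exp(-d * z)` (capped at probability 1), where `z` is the standardized
#'   local H3K9me2 signal. Positive `d` depletes heterochromatic CHH and
#'   inflates euchromatic CHH, the behaviour of a CHG-methylase knockout.
#'
#' @return an object of class `genotype_effect`.
#' @seealso [genotype_preset()] for the study genotypes.
#' @export
genotype_effect <- function(name = "custom", r_cg = 1, r_chg = 1, r_chh = 1,
                            subcontext_retention = NULL,
                            chh_redistribution = 0) {
  r <- c(CG = r_cg, CHG = r_chg, CHH = r_chh)
  if (any(r < 0 | r > 1)) stop("retention factors must lie in [0, 1]")
  if (!is.null(subcontext_retention)) {
    if (is.null(names(subcontext_retention)) || any(!nzchar(names(subcontext_retention))))
      stop("subcontext_retention must be a named numeric vector")
    if (any(subcontext_retention < 0 | subcontext_retention > 1))
      stop("subcontext retention factors must lie in [0, 1]")
  }
  if (chh_redistribution < 0) stop("chh_redistribution must be >= 0")
  structure(list(name = name, retention = r,
                 subcontext_retention = subcontext_retention,
                 chh_redistribution = chh_redistribution),
            class = "genotype_effect")
}

#' Preset genotype effects
#'
#' The knockout genotypes the simulator emulates. Retention factors encode
#' the reported context-specific losses: the CG maintenance methylase mutant
#' (`"met"`) retains 7% of CG methylation, the chromomethylase mutant
#' (`"cmt"`) retains 3% of CHG methylation and redistributes CHH along the
#' chromatin gradient, and the DNMT3-family mutant (`"dnmt3b"`) retains 5% of
#' CHH methylation with a secondary 13% CG loss. `"identity"` (wild type)
#' leaves the methylome untouched.
#'
#' @param name one of `"identity"`, `"met"`, `"cmt"`, `"dnmt3b"`, `"dnmt3ab"`.
#' @return a [genotype_effect()].
#' @export
genotype_preset <- function(name = c("identity", "met", "cmt", "dnmt3b", "dnmt3ab")) {
  name <- match.arg(name)
  switch(name,
    identity = genotype_effect("identity"),
    met      = genotype_effect("met", r_cg = 0.07),
    cmt      = genotype_effect("cmt", r_chg = 0.03, chh_redistribution = 0.7),
    dnmt3b   = genotype_effect("dnmt3b", r_cg = 0.87, r_chh = 0.05),
    dnmt3ab  = genotype_effect("dnmt3ab", r_cg = 0.87, r_chh = 0.05))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "x", x$chrom_length, "bp nuclear +",
      x$organelle_length, "bp organelle;", x$te_count, "TEs,",
      x$gene_count, "genes; depth", x$depth, "x; seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.genotype_effect <- function(x, ...) {
  cat("genotype_effect <", x$name, ">: retention CG=", x$retention["CG"],
      " CHG=", x$retention["CHG"], " CHH=", x$retention["CHH"],
      if (x$chh_redistribution > 0) paste0("; CHH redistribution d=", x$chh_redistribution),
      "\n", sep = "")
  invisible(x)
}
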