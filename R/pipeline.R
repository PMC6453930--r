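#' Pipeline configuration
#'
#' Bundles every stage parameter of the simulate -> align -> call ->
#' window -> DMR chain. Unknown keys are rejected so configurations
#' round-trip losslessly.
#'
#' @param sim a [sim_config()].
#' @param effect mutant [genotype_effect()] (or preset name) compared
#'   against wild type; `NULL` runs wild type only.
#' @param base_levels wild-type per-context TE methylation targets.
#' @param max_mismatches aligner mismatch cap.
#' @param seed_k aligner seed k-mer length.
#' @param window,step window tiling (bp).
#' @param dmr_context context for DMR calling.
#' @param min_fraction,min_informative,alpha DMR filters.
#' @param outdir output directory.
#' @param ... rejected (guards against typo'd keys).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), effect = "cmt",
                            base_levels = c(CG = 0.8, CHG = 0.7, CHH = 0.2),
                            max_mismatches = 2L, seed_k = 20L,
                            window = 50L, step = window,
                            dmr_context = "CHH", min_fraction = 0.1,
                            min_informative = 10L, alpha = 0.05,
                            outdir = tempfile("mossmeth_run_"), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  if (is.character(effect)) effect <- genotype_preset(effect)
  structure(list(sim = sim, effect = effect, base_levels = base_levels,
                 max_mismatches = as.integer(max_mismatches),
                 seed_k = as.integer(seed_k), window = as.integer(window),
                 step = as.integer(step), dmr_context = dmr_context,
                 min_fraction = min_fraction,
                 min_informative = as.integer(min_informative),
                 alpha = alpha, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate -> align -> call -> window (-> DMR when a mutant
#' effect is configured) and writes every artifact plus a JSON manifest
#' (package version, parameters, seed, output checksums, per-stage counts)
#' to the output directory. Reruns with the same configuration reproduce
#' byte-identical TSV outputs. A pre-computed pileup can be supplied to skip
#' the simulation/alignment stages.
#'
#' @param config a [pipeline_config()].
#' @param pileup_wt,pileup_mut optional pre-computed pileup tables; when
#'   given (with `genome`), simulation of reads and alignment are skipped
#'   for that sample.
#' @param genome optional pre-built [simulate_genome()] object to reuse.
#' @return (invisibly) list with all in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config, pileup_wt = NULL, pileup_mut = NULL,
                         genome = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  if (is.null(genome)) genome <- simulate_genome(config$sim)
  write_fasta(genome$seq, file.path(config$outdir, "genome.fa"))
  write_gff(genome$features, file.path(config$outdir, "features.gff3"))
  counts$chromosomes <- nrow(genome$chrom_info)
  counts$features <- nrow(genome$features)

  model_wt <- simulate_methylome(genome, base_levels = config$base_levels)
  model_mut <- if (!is.null(config$effect) &&
                   config$effect$name != "identity")
    apply_genotype_effect(model_wt, config$effect) else NULL

  run_sample <- function(model, tag, pile, seed_offset) {
    if (is.null(pile)) {
      rs <- simulate_bisulfite_reads(genome, model, config$sim,
                                     seed = config$sim$seed + seed_offset)
      write_fastq(rs, file.path(config$outdir, paste0("reads_", tag, ".fastq")))
      counts[[paste0("reads_", tag)]] <<- nrow(rs$reads)
      idx <- build_converted_index(genome, k = config$seed_k)
      aln <- align_reads(rs, idx, max_mismatches = config$max_mismatches)
      counts[[paste0("aligned_", tag)]] <<- sum(aln$status == "unique")
      pile <- pileup(aln, genome)
    }
    data.table::fwrite(pile, file.path(config$outdir,
                                       paste0("pileup_", tag, ".tsv")),
                       sep = "\t")
    calls <- call_single_c(pile, genome)
    counts[[paste0("cytosines_", tag)]] <<- nrow(calls)
    write_single_c(calls, file.path(config$outdir,
                                    paste0("singlec_", tag, ".tsv")))
    w <- window_methylation(calls, window = config$window, step = config$step)
    write_w50(w, file.path(config$outdir, paste0("w50_", tag, ".tsv")))
    list(calls = calls, windows = w)
  }

  wt <- run_sample(model_wt, "wt", pileup_wt, seed_offset = 101L)
  res <- list(genome = genome, model_wt = model_wt, wt = wt)

  if (!is.null(model_mut)) {
    mut <- run_sample(model_mut, "mut", pileup_mut, seed_offset = 202L)
    dmr <- call_dmrs(wt$windows, mut$windows, context = config$dmr_context,
                     min_fraction = config$min_fraction,
                     min_informative = config$min_informative,
                     alpha = config$alpha)
    data.table::fwrite(dmr$dmrs, file.path(config$outdir, "dmrs.tsv"),
                       sep = "\t")
    counts$windows_tested <- dmr$n_tested
    counts$dmrs <- nrow(dmr$dmrs)
    res$mut <- mut
    res$dmr <- dmr
  }

  tsvs <- list.files(config$outdir, pattern = "\\.(tsv|fa|gff3|fastq)$",
                     full.names = TRUE)
  manifest <- list(
    package = "mossmeth",
    version = as.character(packageVersion("mossmeth")),
    seed = config$sim$seed,
    parameters = config_to_list(config),
    stage_counts = counts,
    checksums = as.list(tools::md5sum(sort(tsvs))))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest_path
  invisible(res)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  if (!is.null(out$effect)) {
    out$effect <- unclass(out$effect)
    out$effect$retention <- as.list(out$effect$retention)
    if (!is.null(out$effect$subcontext_retention))
      out$effect$subcontext_retention <- as.list(out$effect$subcontext_retention)
  }
  out$base_levels <- as.list(out$base_levels)
  out
}
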