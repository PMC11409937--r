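#' Simulate a complete community-fitness experiment
#'
#' Generates, at the configured scale: genome + annotation, a barcoded
#' insertion library with mapping reads, planted condition-dependent
#' fitness effects, per-sample BarSeq count matrices, and a dilution-plating
#' growth assay. When `out_dir` is given the standard files (FASTA, GFF3,
#' mapping FASTQ, pool/effects/sample-sheet/plate-count TSVs) are written so
#' they round-trip through the package's own readers; BarSeq FASTQ emission
#' is left to [simulate_barseq_reads()] because at realistic depth it is by
#' far the largest artifact.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @param ... passed to [simulate_effects()] (class sizes, effect sizes).
#' @return list: `genome`, `library` (pool + mapping reads), `effects`,
#'   `counts` (a `barcode_counts` object), `plates` (plate-count table),
#'   `config`.
#' @export
simulate_community <- function(cfg = sim_config(), out_dir = NULL, ...) {
  genome <- simulate_genome(cfg)
  lib <- simulate_library(genome, cfg)
  eff <- simulate_effects(genome$genes, cfg, ...)
  counts <- simulate_selection(lib$pool, eff, cfg)
  scenario <- default_growth_scenario(cfg$conditions)
  plates <- simulate_growth_assay(scenario, n_bio = cfg$n_replicates,
                                  seed = cfg$seed)
  out <- list(genome = genome, library = lib, effects = eff,
              counts = counts, plates = plates, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(genome, file.path(out_dir, "genome.fasta"))
    write_annotation(genome$genes, file.path(out_dir, "genes.gff3"),
                     genome$seqname)
    write_fastq(lib$reads, file.path(out_dir, "mapping_reads.fastq"))
    write_tsv(lib$pool, file.path(out_dir, "pool_truth.tsv"))
    eff_long <- data.frame(
      locus_tag = rep(rownames(eff$effects), ncol(eff$effects)),
      condition = rep(colnames(eff$effects), each = nrow(eff$effects)),
      fitness = as.vector(eff$effects), stringsAsFactors = FALSE)
    write_tsv(eff_long, file.path(out_dir, "true_effects.tsv"))
    write_tsv(eff$classes, file.path(out_dir, "gene_classes.tsv"))
    write_counts(counts, file.path(out_dir, "barcode_counts.tsv"))
    write_tsv(counts$sample_sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_tsv(plates, file.path(out_dir, "plate_counts.tsv"))
  }
  out
}

#' Run the fitness pipeline on a simulated experiment
#'
#' Applies the count filters, per-replicate fitness with both
#' normalizations, moderated t-scores, replicate averaging, and pleiotropy
#' classification; returns everything alongside the simulation truth for
#' recovery checks.
#'
#' @param sim output of [simulate_community()] (or a compatible list).
#' @param min_t0,min_gene_reads,window,pseudocount,t_threshold pipeline
#'   parameters, see [filter_counts()], [replicate_fitness()] and
#'   [aggregate_replicates()].
#' @return list: `filtered`, `fitness` (per_replicate + fitness_table),
#'   `pleiotropy`, `membership`, and `truth` (planted effects and classes).
#' @export
run_community_analysis <- function(sim, min_t0 = 3L, min_gene_reads = 30L,
                                   window = 251L, pseudocount = 0.5,
                                   t_threshold = 3) {
  fc <- filter_counts(sim$counts, sim$library$pool,
                      min_t0 = min_t0, min_gene_reads = min_gene_reads)
  fit <- fitness_analysis(fc, sim$genome$genes, window = window,
                          pseudocount = pseudocount,
                          t_threshold = t_threshold)
  comp <- condition_composition(sim$config)
  pl <- classify_pleiotropy(fit$fitness_table, comp)
  mem <- membership_counts(fit$fitness_table)
  list(filtered = fc, fitness = fit, pleiotropy = pl, membership = mem,
       truth = sim$effects)
}

#' Planted-versus-estimated fitness recovery
#'
#' Joins the planted per-gene, per-condition fitness with the estimated
#' FitnessTable and reports the Pearson correlation, optionally restricted
#' to genes supported by at least `min_strains` retained insertion strains.
#'
#' @param analysis output of [run_community_analysis()].
#' @param min_strains minimum retained strains per gene (0 disables).
#' @return list: `pairs` (locus_tag, condition, planted, estimated,
#'   n_strains), `pearson_r`.
#' @export
fitness_recovery <- function(analysis, min_strains = 10L) {
  ft <- analysis$fitness$fitness_table
  eff <- analysis$truth$effects
  planted <- eff[cbind(match(ft$locus_tag, rownames(eff)),
                       match(ft$condition, colnames(eff)))]
  ns <- analysis$filtered$gene_totals$n_barcodes[
    match(ft$locus_tag, analysis$filtered$gene_totals$locus_tag)]
  pairs <- data.frame(locus_tag = ft$locus_tag, condition = ft$condition,
                      planted = planted, estimated = ft$fitness,
                      n_strains = ns, stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$planted), , drop = FALSE]
  use <- pairs[pairs$n_strains >= min_strains, , drop = FALSE]
  list(pairs = pairs,
       pearson_r = stats::cor(use$planted, use$estimated))
}
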