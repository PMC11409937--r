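#' Read layouts used by the simulator and the extractors
#'
#' Transposon-junction (mapping) reads are laid out as
#' `barcode | junction tag | genomic flank`; the junction tag is the 19-bp
#' Tn5 mosaic end. BarSeq amplicon reads are laid out as
#' `left flank | barcode | right flank`, mirroring the standard BarSeq
#' amplicon structure around the 20-bp random barcode.
#'
#' @param junction_tag fixed sequence separating the barcode from genomic DNA
#'   in mapping reads.
#' @param barcode_length barcode length in bp.
#' @param min_flank minimum genomic flank (bp) required to attempt mapping;
#'   also the k-mer size used for unique placement.
#' @param left_flank,right_flank fixed sequences flanking the barcode in
#'   BarSeq reads.
#' @return A named list describing the layout.
#' @export
tn_layout <- function(junction_tag = "CTGTCTCTTATACACATCT",
                      barcode_length = 20L,
                      min_flank = 20L) {
  stopifnot(nchar(junction_tag) > 0, barcode_length >= 8, min_flank >= 10)
  list(junction_tag = junction_tag,
       barcode_length = as.integer(barcode_length),
       min_flank = as.integer(min_flank))
}

#' @rdname tn_layout
#' @export
barseq_layout <- function(left_flank = "GTCGACCTGCAGCGTACG",
                          right_flank = "AGAGACC",
                          barcode_length = 20L) {
  stopifnot(nchar(left_flank) > 0, nchar(right_flank) > 0, barcode_length >= 8)
  list(left_flank = left_flank,
       right_flank = right_flank,
       barcode_length = as.integer(barcode_length))
}

#' Configuration for the synthetic community generator
#'
#' Defaults describe the desk-scale study system: a 200-kb bacterial genome
#' with 150 genes covering 85% of the sequence, a Tn5 library of 10,000
#' barcoded insertions, and a four-condition community experiment (growth
#' alone, with lytic phage, with two fungi, and with both) sampled at
#' inoculation (T0) and after three days, in three biological replicates,
#' at 5e5 BarSeq reads per sample. The full study scale (1.6e5 insertions,
#' thousands of genes, hundreds of millions of reads) is reachable by raising
#' these numbers; the statistical structure is identical.
#'
#' @param genome_length genome size in bp.
#' @param n_genes number of protein-coding genes to place.
#' @param coding_fraction fraction of the genome covered by genes, in (0, 1].
#' @param n_insertions number of barcoded transposon insertions.
#' @param barcode_length random barcode length in bp (>= 8).
#' @param conditions character vector of growth-condition labels.
#' @param has_phage,has_fungi logical vectors parallel to `conditions`
#'   declaring each condition's community composition (used for pleiotropy
#'   classification; never inferred from labels downstream).
#' @param n_replicates biological replicates per condition.
#' @param days length of the selection experiment in days.
#' @param read_depth_per_sample BarSeq reads per sample.
#' @param reads_per_insertion junction-mapping reads emitted per insertion.
#' @param chimera_fraction fraction of barcodes emitted at two genomic
#'   locations (chimeric artifacts, for negative testing).
#' @param junk_read_fraction fraction of extra junction-free mapping reads.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(genome_length = 200000L,
                       n_genes = 150L,
                       coding_fraction = 0.85,
                       n_insertions = 10000L,
                       barcode_length = 20L,
                       conditions = c("alone", "phage", "fungi", "phage_fungi"),
                       has_phage = c(FALSE, TRUE, FALSE, TRUE),
                       has_fungi = c(FALSE, FALSE, TRUE, TRUE),
                       n_replicates = 3L,
                       days = 3L,
                       read_depth_per_sample = 500000L,
                       reads_per_insertion = 3L,
                       chimera_fraction = 0,
                       junk_read_fraction = 0,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              coding_fraction = coding_fraction,
              n_insertions = as.integer(n_insertions),
              barcode_length = as.integer(barcode_length),
              conditions = conditions,
              has_phage = has_phage,
              has_fungi = has_fungi,
              n_replicates = as.integer(n_replicates),
              days = as.integer(days),
              read_depth_per_sample = as.integer(read_depth_per_sample),
              reads_per_insertion = as.integer(reads_per_insertion),
              chimera_fraction = chimera_fraction,
              junk_read_fraction = junk_read_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0, cfg$n_genes > 0, cfg$n_insertions > 0,
            cfg$n_replicates > 0, cfg$days > 0,
            cfg$read_depth_per_sample > 0, cfg$reads_per_insertion > 0)
  if (!(cfg$coding_fraction > 0 && cfg$coding_fraction <= 1))
    stop("coding_fraction must lie in (0, 1]")
  if (cfg$barcode_length < 8)
    stop("barcode_length must be >= 8")
  if (length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions))
    stop("conditions must be a non-empty set of unique labels")
  if (length(cfg$has_phage) != length(cfg$conditions) ||
      length(cfg$has_fungi) != length(cfg$conditions))
    stop("has_phage / has_fungi must parallel the conditions vector")
  if (cfg$chimera_fraction < 0 || cfg$chimera_fraction > 0.5)
    stop("chimera_fraction must lie in [0, 0.5]")
  # genes of >= 30 bp must fit: mean gene length must be feasible
  if (cfg$n_genes * 30 > cfg$coding_fraction * cfg$genome_length)
    stop("infeasible gene packing: n_genes too large for coding_fraction * genome_length")
  invisible(cfg)
}

#' Condition composition table from a config or sample sheet
#'
#' @param cfg a `sim_config`.
#' @return data.frame with columns condition, has_phage, has_fungi.
#' @export
condition_composition <- function(cfg) {
  data.frame(condition = cfg$conditions,
             has_phage = cfg$has_phage,
             has_fungi = cfg$has_fungi,
             stringsAsFactors = FALSE)
}
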