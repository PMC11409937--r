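#' Plant condition-dependent fitness effects on genes
#'
#' Assigns gene classes and per-condition planted fitness values (log2 units
#' over the experiment). Defaults encode the trade-off structure of a
#' phage/fungus community experiment: antagonistically pleiotropic genes
#' (O-antigen-like) gain fitness in every phage-containing condition and
#' lose fitness in the fungi-only condition; phage-benefit genes gain only
#' under phage; fungus-cost genes lose in every fungi-containing condition;
#' generally deleterious genes lose everywhere; all remaining genes (the
#' large majority, as mode normalization assumes) are exactly neutral.
#'
#' @param genes gene table from [simulate_genome()].
#' @param cfg a [sim_config()] (supplies conditions and their composition).
#' @param n_antagonistic,n_phage_benefit,n_fungus_cost,n_deleterious gene
#'   counts per non-neutral class.
#' @param effect_phage planted fitness of antagonistic / phage-benefit genes
#'   in phage-containing conditions (default +2).
#' @param effect_fungi planted fitness of antagonistic genes in fungi-only
#'   and of fungus-cost genes in fungi-containing conditions (default -1.5).
#' @param effect_deleterious planted fitness of generally deleterious genes
#'   (default -2).
#' @param seed optional integer overriding `cfg$seed`.
#' @return list with `classes` (data.frame: locus_tag, class) and `effects`
#'   (matrix genes x conditions of planted fitness).
#' @export
simulate_effects <- function(genes, cfg,
                             n_antagonistic = 6L, n_phage_benefit = 6L,
                             n_fungus_cost = 6L, n_deleterious = 6L,
                             effect_phage = 2, effect_fungi = -1.5,
                             effect_deleterious = -2, seed = cfg$seed) {
  set.seed(seed + 2L)
  n <- nrow(genes)
  n_special <- n_antagonistic + n_phage_benefit + n_fungus_cost + n_deleterious
  if (n_special > 0.2 * n)
    stop("non-neutral classes exceed 20% of genes; the mode-normalization ",
         "assumption (neutral majority) would not hold")
  comp <- condition_composition(cfg)
  if (n_antagonistic + n_phage_benefit > 0 && !any(comp$has_phage))
    stop("planting phage-responsive effects requires a phage-containing ",
         "condition")
  if (n_antagonistic > 0 && !any(!comp$has_phage & comp$has_fungi))
    stop("planting antagonistic effects requires a fungi-only condition")
  if (n_fungus_cost > 0 && !any(comp$has_fungi))
    stop("planting fungus-cost effects requires a fungi-containing condition")

  picked <- sample.int(n, n_special)
  cls <- rep("neutral", n)
  splits <- rep(c("antagonistic-pleiotropic", "phage-benefit", "fungus-cost",
                  "generally-deleterious"),
                c(n_antagonistic, n_phage_benefit, n_fungus_cost,
                  n_deleterious))
  cls[picked] <- splits

  eff <- matrix(0, nrow = n, ncol = nrow(comp),
                dimnames = list(genes$locus_tag, comp$condition))
  for (j in seq_len(nrow(comp))) {
    phage <- comp$has_phage[j]
    fungi <- comp$has_fungi[j]
    e <- numeric(n)
    e[cls == "antagonistic-pleiotropic"] <-
      if (phage) effect_phage else if (fungi) effect_fungi else 0
    e[cls == "phage-benefit"] <- if (phage) effect_phage else 0
    e[cls == "fungus-cost"] <- if (fungi) effect_fungi else 0
    e[cls == "generally-deleterious"] <- effect_deleterious
    eff[, j] <- e
  }
  list(classes = data.frame(locus_tag = genes$locus_tag, class = cls,
                            stringsAsFactors = FALSE),
       effects = eff)
}

#' Simulate selection and BarSeq counting over the community experiment
#'
#' Strain abundances at day 3 are proportional to `a0 * 2^f`, the generative
#' inverse of the log2 fitness definition, where `a0` is the strain's
#' (lognormal) inoculum abundance and `f` the planted fitness of its gene in
#' that condition (intergenic strains inherit f = 0). Sequencing is
#' multinomial at `read_depth_per_sample`: one T0 sample drawn from the
#' unselected library and one day-3 sample per condition x replicate.
#'
#' @param pool annotated InsertionPool truth from [simulate_library()].
#' @param effects output of [simulate_effects()].
#' @param cfg a [sim_config()].
#' @param abundance_sdlog lognormal sd of inoculum strain abundances.
#' @param seed optional integer overriding `cfg$seed`.
#' @return a `barcode_counts` object (see [build_count_matrix()]) whose
#'   sample sheet carries condition composition columns, plus attribute
#'   `"true_freq0"` (inoculum relative abundances).
#' @export
simulate_selection <- function(pool, effects, cfg, abundance_sdlog = 0.5,
                               seed = cfg$seed) {
  set.seed(seed + 3L)
  pool <- pool[!duplicated(pool$barcode), , drop = FALSE]  # chimeras: 1st loc
  n <- nrow(pool)
  f_by_gene <- effects$effects
  gene_idx <- match(pool$locus_tag, rownames(f_by_gene))

  a0 <- stats::rlnorm(n, meanlog = 0, sdlog = abundance_sdlog)
  p0 <- a0 / sum(a0)
  if (all(!is.finite(f_by_gene)))
    stop("all planted fitness values are -Inf: library would be extinct")

  comp <- condition_composition(cfg)
  sheet <- data.frame(sample = "T0", condition = "T0", replicate = 0L,
                      timepoint = "T0", has_phage = FALSE, has_fungi = FALSE,
                      stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow = n,
                   ncol = 1L + nrow(comp) * cfg$n_replicates,
                   dimnames = list(pool$barcode, NULL))
  counts[, 1] <- stats::rmultinom(1, cfg$read_depth_per_sample, p0)[, 1]
  col <- 1L
  for (j in seq_len(nrow(comp))) {
    f <- f_by_gene[, comp$condition[j]][gene_idx]
    f[is.na(f)] <- 0  # intergenic strains are neutral
    a3 <- a0 * 2^f
    p3 <- a3 / sum(a3)
    for (r in seq_len(cfg$n_replicates)) {
      col <- col + 1L
      counts[, col] <- stats::rmultinom(1, cfg$read_depth_per_sample, p3)[, 1]
      sheet <- rbind(sheet, data.frame(
        sample = sprintf("%s_rep%d", comp$condition[j], r),
        condition = comp$condition[j], replicate = r, timepoint = "day3",
        has_phage = comp$has_phage[j], has_fungi = comp$has_fungi[j],
        stringsAsFactors = FALSE))
    }
  }
  colnames(counts) <- sheet$sample
  structure(list(counts = counts, known = rep(TRUE, n), sample_sheet = sheet,
                 true_freq0 = p0),
            class = "barcode_counts")
}

#' Emit BarSeq FASTQ-style reads from a count matrix
#'
#' Each read is `left flank | barcode | right flank` per [barseq_layout()],
#' with independent per-base substitution errors at `error_rate`. At error
#' rate 0 the multiset of reads per sample reproduces the count matrix
#' exactly.
#'
#' @param bc a `barcode_counts` object (or plain integer matrix with barcode
#'   rownames).
#' @param layout a [barseq_layout()].
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return named list (per sample) of character read vectors; attribute
#'   `"n_errors"` records the committed number of substituted bases per
#'   sample.
#' @export
simulate_barseq_reads <- function(bc, layout = barseq_layout(),
                                  error_rate = 0, seed = 1L) {
  counts <- if (inherits(bc, "barcode_counts")) bc$counts else bc
  stopifnot(all(counts >= 0))
  set.seed(seed + 4L)
  alphabet <- c("A", "C", "G", "T")
  out <- lapply(colnames(counts), function(s) {
    bcv <- rep(rownames(counts), counts[, s])
    reads <- paste0(layout$left_flank, bcv, layout$right_flank)
    n_err <- 0L
    if (error_rate > 0 && length(reads) > 0) {
      width <- nchar(reads[1])
      n_bases <- length(reads) * width
      n_err <- stats::rbinom(1, n_bases, error_rate)
      if (n_err > 0) {
        sites <- sample.int(n_bases, n_err)
        ri <- (sites - 1L) %/% width + 1L
        pi <- (sites - 1L) %% width + 1L
        for (k in seq_len(n_err)) {
          old <- substring(reads[ri[k]], pi[k], pi[k])
          new <- sample(setdiff(alphabet, old), 1)
          substr(reads[ri[k]], pi[k], pi[k]) <- new
        }
      }
    }
    if (length(reads) > 0) reads <- sample(reads)  # shuffle read order
    attr(reads, "n_errors") <- n_err
    reads
  })
  names(out) <- colnames(counts)
  out
}
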