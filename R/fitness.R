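#' Raw strain fitness: log2 change in relative barcode abundance
#'
#' `f = log2( ((n_day3 + eps)/N_day3) / ((n_t0 + eps)/N_t0) )` with
#' pseudocount `eps = 0.5`. Abundance is within-sample relative abundance,
#' so fitness is invariant to sequencing depth; the pseudocount keeps the
#' ratio finite for barcodes that drop to zero reads.
#'
#' @param n_day3,n_t0 barcode read counts in the day-3 and T0 samples.
#' @param total_day3,total_t0 total retained reads in each sample.
#' @param pseudocount additive pseudocount (default 0.5).
#' @return numeric vector of raw strain fitness values (log2 units per
#'   experiment).
#' @export
strain_fitness <- function(n_day3, n_t0, total_day3, total_t0,
                           pseudocount = 0.5) {
  stopifnot(all(n_day3 >= 0), all(n_t0 >= 0),
            total_day3 > 0, total_t0 > 0)
  log2(((n_day3 + pseudocount) / total_day3) /
         ((n_t0 + pseudocount) / total_t0))
}

#' Inverse-variance strain weights
#'
#' `w = 2 / (1/(1 + n_t0) + 1/(1 + n_day3))`: the harmonic combination of
#' the two count-limited precision terms, so well-sequenced strains dominate
#' the gene average.
#'
#' @param n_t0,n_day3 barcode read counts.
#' @return numeric weights, strictly positive.
#' @export
strain_weight <- function(n_t0, n_day3) {
  2 / (1 / (1 + n_t0) + 1 / (1 + n_day3))
}

#' Raw gene fitness: weighted mean of strain fitness
#'
#' @param f strain fitness values.
#' @param w strain weights from [strain_weight()].
#' @return weighted mean.
#' @export
gene_fitness <- function(f, w) {
  stopifnot(length(f) >= 1, length(f) == length(w), all(w > 0))
  sum(w * f) / sum(w)
}

#' Chromosomal-position normalization by circular running median
#'
#' Subtracts from each gene's fitness the median over a centered window of
#' `window` genes (default 251) ordered by chromosomal midpoint, with
#' circular wrap-around. This removes the copy-number trend created by
#' genes near the replication fork being present in more copies in growing
#' cells. When fewer genes than the window exist, the window is truncated to
#' the largest odd number not exceeding the gene count.
#'
#' @param f gene fitness values.
#' @param midpoint gene chromosomal midpoints (same length as `f`).
#' @param window window size in genes (odd; even values are decremented).
#' @return fitness values with the smoothed median removed, in input order.
#' @export
normalize_position <- function(f, midpoint, window = 251L) {
  n <- length(f)
  stopifnot(length(midpoint) == n, n >= 1)
  w <- min(window, n)
  if (w %% 2 == 0) w <- w - 1L
  if (w < 1) w <- 1L
  ord <- order(midpoint)
  fo <- f[ord]
  h <- (w - 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    idx <- ((i - 1L + seq.int(-h, h)) %% n) + 1L
    stats::median(fo[idx])
  }, numeric(1))
  out <- f
  out[ord] <- fo - med
  out
}

#' Mode normalization of the gene-fitness distribution
#'
#' Most insertions are assumed neutral, so the mode of the fitness
#' distribution should sit at zero. The mode is estimated as the center of
#' the maximal-count histogram bin, with bins of width `bin_width` (default
#' 0.05) centered on integer multiples of the width, over the central 95% of
#' values (robust to tails); ties between bins are broken toward 0. The
#' estimated mode is subtracted from every value.
#'
#' @param f gene fitness values (>= 10 values required).
#' @param bin_width histogram bin width (default 0.05).
#' @return list with `f` (mode-subtracted values) and `mode` (the subtracted
#'   estimate).
#' @export
normalize_mode <- function(f, bin_width = 0.05) {
  stopifnot(length(f) >= 10)
  qs <- stats::quantile(f, c(0.025, 0.975), names = FALSE, type = 7)
  sel <- f[f >= qs[1] & f <= qs[2]]
  bins <- round(sel / bin_width)
  tab <- table(bins)
  centers <- as.numeric(names(tab)) * bin_width
  best <- which(tab == max(tab))
  # tie-break toward 0 (then deterministically toward the smaller center)
  best <- best[order(abs(centers[best]), centers[best])][1]
  mode_est <- centers[best]
  list(f = f - mode_est, mode = mode_est)
}

#' Moderated t-score for a gene's fitness
#'
#' `t = f / sqrt(V)` where `V` is the larger of (a) the weighted
#' between-strain variance of strain fitness divided by the effective strain
#' number `(sum w)^2 / sum(w^2)`, and (b) a count-limited variance floor
#' `(1/ln 2)^2 * (1/(1 + N_t0) + 1/(1 + N_day3))` with `N` the gene's summed
#' reads per timepoint. The floor prevents genes whose strains agree by
#' chance (or single-strain genes) from getting unrealistically confident
#' scores.
#'
#' @param f_final the gene's final (normalized) fitness.
#' @param f_strains strain fitness values for the gene.
#' @param w strain weights.
#' @param n_t0_gene,n_day3_gene the gene's total reads at T0 and day 3.
#' @param f_gene_raw the gene's raw fitness (weighted mean of `f_strains`);
#'   recomputed when missing.
#' @return the t-score (finite).
#' @export
gene_t_score <- function(f_final, f_strains, w, n_t0_gene, n_day3_gene,
                         f_gene_raw = NULL) {
  if (is.null(f_gene_raw)) f_gene_raw <- gene_fitness(f_strains, w)
  v_between <- sum(w * (f_strains - f_gene_raw)^2) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  v_floor <- (1 / log(2))^2 *
    (1 / (1 + n_t0_gene) + 1 / (1 + n_day3_gene))
  v <- max(v_between / n_eff, v_floor)
  f_final / sqrt(v)
}

#' Per-replicate gene fitness for one day-3 sample against T0
#'
#' Runs the full per-sample chain: strain fitness and weights, weighted
#' per-gene means, smoothed-median (positional) normalization, mode
#' normalization, and moderated t-scores.
#'
#' @param fc a `filtered_counts` object from [filter_counts()].
#' @param sample day-3 sample label (a column of the filtered matrix).
#' @param genes gene table (for chromosomal midpoints).
#' @param window running-median window (genes).
#' @param pseudocount pseudocount for [strain_fitness()].
#' @return data.frame: locus_tag, fitness_raw, fitness_pos (position
#'   normalized), fitness (final), t, n_strains, reads_t0, reads_day3.
#' @export
replicate_fitness <- function(fc, sample, genes, window = 251L,
                              pseudocount = 0.5) {
  stopifnot(inherits(fc, "filtered_counts"),
            sample %in% colnames(fc$counts), sample != fc$t0_sample)
  n0 <- fc$counts[, fc$t0_sample]
  n3 <- fc$counts[, sample]
  N0 <- sum(n0)
  N3 <- sum(n3)
  fs <- strain_fitness(n3, n0, N3, N0, pseudocount)
  w <- strain_weight(n0, n3)
  gene <- fc$strains$locus_tag

  split_idx <- split(seq_along(gene), gene)
  res <- data.frame(locus_tag = names(split_idx), stringsAsFactors = FALSE)
  res$fitness_raw <- vapply(split_idx, function(i) gene_fitness(fs[i], w[i]),
                            numeric(1))
  res$n_strains <- lengths(split_idx)
  res$reads_t0 <- vapply(split_idx, function(i) sum(n0[i]), numeric(1))
  res$reads_day3 <- vapply(split_idx, function(i) sum(n3[i]), numeric(1))

  mid <- genes$midpoint[match(res$locus_tag, genes$locus_tag)]
  if (anyNA(mid))
    stop("genes present in the counts are missing from the annotation")
  res$fitness_pos <- normalize_position(res$fitness_raw, mid, window)
  nm <- normalize_mode(res$fitness_pos)
  res$fitness <- nm$f
  res$t <- vapply(seq_len(nrow(res)), function(j) {
    i <- split_idx[[j]]
    gene_t_score(res$fitness[j], fs[i], w[i],
                 res$reads_t0[j], res$reads_day3[j],
                 f_gene_raw = res$fitness_raw[j])
  }, numeric(1))
  attr(res, "mode_shift") <- nm$mode
  rownames(res) <- NULL
  res
}

#' Average per-replicate fitness into a condition-level table
#'
#' Fitness and t-scores are averaged arithmetically across the biological
#' replicates of each condition (genes failing filters in some replicate are
#' averaged over the replicates where they are defined, with the replicate
#' count reported). A gene has a strong effect when `|mean t| >=
#' t_threshold` (default 3); strong-positive additionally requires mean
#' fitness > 0.
#'
#' @param per_rep data.frame of per-replicate results: columns locus_tag,
#'   condition, replicate, fitness, t (e.g. rows bound from
#'   [replicate_fitness()]).
#' @param t_threshold strong-effect threshold on `|mean t|`.
#' @return data.frame (the FitnessTable): locus_tag, condition, fitness, t,
#'   n_replicates, strong, effect ("positive" / "negative" / "none").
#' @export
aggregate_replicates <- function(per_rep, t_threshold = 3) {
  stopifnot(all(c("locus_tag", "condition", "fitness", "t") %in%
                  colnames(per_rep)))
  key <- interaction(per_rep$locus_tag, per_rep$condition, drop = TRUE)
  agg <- data.frame(
    locus_tag = tapply(per_rep$locus_tag, key, `[`, 1),
    condition = tapply(per_rep$condition, key, `[`, 1),
    fitness = as.numeric(tapply(per_rep$fitness, key, mean)),
    t = as.numeric(tapply(per_rep$t, key, mean)),
    n_replicates = as.integer(tapply(per_rep$t, key, length)),
    stringsAsFactors = FALSE)
  agg$strong <- abs(agg$t) >= t_threshold
  agg$effect <- ifelse(!agg$strong, "none",
                       ifelse(agg$fitness > 0, "positive", "negative"))
  rownames(agg) <- NULL
  agg[order(agg$condition, agg$locus_tag), ]
}

#' Full fitness analysis across all conditions and replicates
#'
#' @param fc a `filtered_counts` object (its sample sheet drives the loop:
#'   every non-T0 sample is analyzed against the T0 reference).
#' @param genes gene table.
#' @param window,pseudocount,t_threshold see [replicate_fitness()] and
#'   [aggregate_replicates()].
#' @return list with `per_replicate` (row-bound [replicate_fitness()] output
#'   with condition/replicate columns) and `fitness_table`
#'   ([aggregate_replicates()] output).
#' @export
fitness_analysis <- function(fc, genes, window = 251L, pseudocount = 0.5,
                             t_threshold = 3) {
  ss <- fc$sample_sheet
  day3 <- ss[ss$timepoint != "T0", , drop = FALSE]
  per_rep <- do.call(rbind, lapply(seq_len(nrow(day3)), function(i) {
    r <- replicate_fitness(fc, day3$sample[i], genes, window, pseudocount)
    r$condition <- day3$condition[i]
    r$replicate <- day3$replicate[i]
    r
  }))
  list(per_replicate = per_rep,
       fitness_table = aggregate_replicates(per_rep, t_threshold))
}
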