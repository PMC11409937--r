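#' Extract and tally barcodes from BarSeq reads of one sample
#'
#' Reads follow the fixed-position [barseq_layout()]:
#' `left flank | barcode | right flank`. A read yields a barcode when both
#' flanks match their templates with at most `max_mismatch` mismatched bases
#' in total (default 0, exact matching); other reads are rejected. Reads too
#' short to contain the full layout are rejected as well.
#'
#' @param reads character vector of read sequences or a FASTQ path.
#' @param layout a [barseq_layout()].
#' @param max_mismatch maximum summed Hamming mismatches over both flanks.
#' @return list with `tally` (named integer vector of barcode counts) and
#'   `n_rejected`.
#' @export
extract_barcodes <- function(reads, layout = barseq_layout(),
                             max_mismatch = 0L) {
  if (length(reads) == 1 && !is.na(reads) && file.exists(reads))
    reads <- read_fastq(reads)
  if (length(reads) == 0)
    return(list(tally = stats::setNames(integer(), character()),
                n_rejected = 0L))
  lf <- layout$left_flank
  rf <- layout$right_flank
  blen <- layout$barcode_length
  need <- nchar(lf) + blen + nchar(rf)
  long_enough <- nchar(reads) >= need

  mm <- integer(length(reads))
  template <- c(strsplit(lf, "")[[1]], strsplit(rf, "")[[1]])
  offsets <- c(seq_len(nchar(lf)),
               nchar(lf) + blen + seq_len(nchar(rf)))
  for (j in seq_along(offsets)) {
    mm <- mm + (substring(reads, offsets[j], offsets[j]) != template[j])
  }
  ok <- long_enough & mm <= max_mismatch
  bc <- substring(reads[ok], nchar(lf) + 1L, nchar(lf) + blen)
  tab <- table(bc)
  list(tally = stats::setNames(as.integer(tab), names(tab)),
       n_rejected = sum(!ok))
}

#' Assemble the barcode-by-sample count matrix
#'
#' @param tallies named list of per-sample barcode tallies (as produced by
#'   [extract_barcodes()], the `tally` element), names = sample labels.
#' @param sample_sheet data.frame with columns sample, condition, replicate,
#'   timepoint (exactly one "T0" row); row per sample, matching the tally
#'   names.
#' @param pool InsertionPool used to flag known vs unknown barcodes; unknown
#'   barcodes are retained and flagged, not silently dropped.
#' @return list of class `barcode_counts`: `counts` (integer matrix barcodes
#'   x samples), `known` (logical per row), `sample_sheet`.
#' @export
build_count_matrix <- function(tallies, sample_sheet, pool) {
  if (anyDuplicated(names(tallies)) || anyDuplicated(sample_sheet$sample))
    stop("duplicate sample labels")
  if (!setequal(names(tallies), sample_sheet$sample))
    stop("tally names and sample sheet labels disagree")
  if (sum(sample_sheet$timepoint == "T0") != 1)
    stop("exactly one T0 reference sample is required")
  tallies <- tallies[sample_sheet$sample]
  barcodes <- sort(unique(unlist(lapply(tallies, names), use.names = FALSE)))
  counts <- vapply(tallies, function(tl) {
    v <- integer(length(barcodes))
    v[match(names(tl), barcodes)] <- as.integer(tl)
    v
  }, integer(length(barcodes)))
  counts <- matrix(counts, nrow = length(barcodes),
                   dimnames = list(barcodes, sample_sheet$sample))
  structure(list(counts = counts,
                 known = barcodes %in% pool$barcode,
                 sample_sheet = sample_sheet),
            class = "barcode_counts")
}

#' Apply the RB-TnSeq count filters
#'
#' Three rules, applied in order, each tallied in the audit log:
#' (1) barcodes not present in the characterized insertion pool are dropped
#' (`unknown`); (2) barcodes counted fewer than `min_t0` times (default 3)
#' in the raw T0 sample are dropped (`low_t0`, strict less-than); (3) only
#' central insertions (relative position 10%-90% of a gene) enter gene-level
#' analysis, so intergenic and terminal barcodes are dropped (`non_central`),
#' and genes whose surviving barcodes sum to fewer than `min_gene_reads`
#' (default 30) T0 reads are excluded with their barcodes (`low_gene_reads`,
#' strict less-than).
#'
#' @param bc a `barcode_counts` object from [build_count_matrix()].
#' @param pool annotated InsertionPool.
#' @param min_t0 minimum raw T0 count per barcode.
#' @param min_gene_reads minimum summed T0 reads per gene.
#' @return list of class `filtered_counts`: `counts` (filtered matrix),
#'   `strains` (data.frame aligning rows to barcode, locus_tag, rel_pos),
#'   `gene_totals` (locus_tag, t0_reads, n_barcodes), `audit` (named integer
#'   removals per rule), `t0_sample`.
#' @export
filter_counts <- function(bc, pool, min_t0 = 3L, min_gene_reads = 30L) {
  if (inherits(bc, "filtered_counts"))
    bc <- structure(list(counts = bc$counts,
                         known = rownames(bc$counts) %in% pool$barcode,
                         sample_sheet = bc$sample_sheet),
                    class = "barcode_counts")
  t0_sample <- bc$sample_sheet$sample[bc$sample_sheet$timepoint == "T0"]
  if (length(t0_sample) != 1 || !t0_sample %in% colnames(bc$counts))
    stop("designated T0 sample missing from the count matrix")
  m <- bc$counts
  audit <- c(unknown = 0L, low_t0 = 0L, non_central = 0L, low_gene_reads = 0L)

  keep <- bc$known
  audit["unknown"] <- sum(!keep)
  m <- m[keep, , drop = FALSE]

  ok_t0 <- m[, t0_sample] >= min_t0
  audit["low_t0"] <- sum(!ok_t0)
  m <- m[ok_t0, , drop = FALSE]

  ann <- pool[match(rownames(m), pool$barcode),
              c("barcode", "locus_tag", "rel_pos", "central")]
  ok_central <- !is.na(ann$locus_tag) & ann$central
  audit["non_central"] <- sum(!ok_central)
  m <- m[ok_central, , drop = FALSE]
  ann <- ann[ok_central, , drop = FALSE]

  t0_by_gene <- tapply(m[, t0_sample], ann$locus_tag, sum)
  good_genes <- names(t0_by_gene)[t0_by_gene >= min_gene_reads]
  ok_gene <- ann$locus_tag %in% good_genes
  audit["low_gene_reads"] <- sum(!ok_gene)
  m <- m[ok_gene, , drop = FALSE]
  ann <- ann[ok_gene, , drop = FALSE]
  rownames(ann) <- NULL

  gt <- data.frame(locus_tag = names(t0_by_gene)[names(t0_by_gene) %in% good_genes],
                   stringsAsFactors = FALSE)
  gt$t0_reads <- as.integer(t0_by_gene[gt$locus_tag])
  gt$n_barcodes <- as.integer(table(ann$locus_tag)[gt$locus_tag])

  structure(list(counts = m, strains = ann, gene_totals = gt,
                 audit = audit, t0_sample = t0_sample,
                 sample_sheet = bc$sample_sheet),
            class = "filtered_counts")
}
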