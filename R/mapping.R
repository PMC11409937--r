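#' Assign insertion positions to genes
#'
#' Computes, for each 0-based junction coordinate, the containing gene (if
#' any), the relative position within the gene measured along the coding
#' strand, and the central-insertion flag. Relative position is
#' `offset / length` for forward-strand genes and `(length - offset) / length`
#' for reverse-strand genes, where `offset` is the 0-based distance from the
#' gene's chromosome-left end. Insertions with relative position in
#' [0.1, 0.9] (boundaries inclusive) are flagged central, the standard
#' disruptive zone for Tn-Seq experiments.
#'
#' @param position integer vector of 0-based genomic coordinates.
#' @param strand insertion strand ("+"/"-"); recorded but not used for gene
#'   assignment (disruption is strand-agnostic).
#' @param genes gene table from [simulate_genome()] or [read_annotation()]
#'   (1-based inclusive start/end, strand, locus_tag).
#' @return data.frame with columns locus_tag (NA if intergenic), rel_pos,
#'   central.
#' @export
assign_gene <- function(position, strand, genes) {
  if (any(position < 0))
    stop("position must be a non-negative 0-based coordinate")
  genes <- genes[order(genes$start), , drop = FALSE]
  pos1 <- position + 1L                      # to 1-based
  idx <- findInterval(pos1, genes$start)
  hit <- idx >= 1 & idx <= nrow(genes)
  hit[hit] <- pos1[hit] <= genes$end[idx[hit]]

  locus <- rep(NA_character_, length(position))
  rel <- rep(NA_real_, length(position))
  central <- rep(FALSE, length(position))
  if (any(hit)) {
    gi <- idx[hit]
    len <- genes$end[gi] - genes$start[gi] + 1L
    offset <- pos1[hit] - genes$start[gi]
    r <- ifelse(genes$strand[gi] == "+", offset / len, (len - offset) / len)
    locus[hit] <- genes$locus_tag[gi]
    rel[hit] <- r
    central[hit] <- r >= 0.1 & r <= 0.9
  }
  data.frame(locus_tag = locus, rel_pos = rel, central = central,
             stringsAsFactors = FALSE)
}

#' Map transposon-junction reads to a genome
#'
#' Locates the fixed junction tag in each read, takes the preceding
#' `barcode_length` bases as the barcode and the following bases as genomic
#' flank, and places the flank's first `min_flank` bases in the genome by
#' exact k-mer lookup on both strands. Reads are discarded (with tallied
#' reasons) when the tag is absent (`no_junction`), the barcode is truncated
#' (`no_barcode`), the flank is shorter than `min_flank` (`short_flank`), the
#' flank is absent from the genome (`unmapped`), or it occurs at more than
#' one site across both strands (`multi_mapped`).
#'
#' @param reads character vector of read sequences (or a FASTQ path, read via
#'   [read_fastq()]).
#' @param genome genome list from [simulate_genome()]/[read_genome()], or a
#'   plain sequence string.
#' @param layout a [tn_layout()].
#' @return list with `observations` (data.frame: barcode, position
#'   (0-based junction coordinate), strand) and `rejected` (named integer
#'   tallies per discard reason).
#' @export
map_insertions <- function(reads, genome, layout = tn_layout()) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq(reads)
  seqn <- if (is.list(genome)) genome$sequence else genome
  if (grepl("[^ACGT]", seqn))
    stop("genome contains characters outside the A/C/G/T alphabet")
  if (length(reads) == 0) {
    warning("empty read set: returning no observations")
    return(list(observations = data.frame(barcode = character(),
                                          position = integer(),
                                          strand = character(),
                                          stringsAsFactors = FALSE),
                rejected = integer()))
  }

  tag <- layout$junction_tag
  blen <- layout$barcode_length
  k <- layout$min_flank
  reasons <- rep(NA_character_, length(reads))

  tag_at <- regexpr(tag, reads, fixed = TRUE)
  reasons[tag_at < 0] <- "no_junction"
  ok <- tag_at > 0
  reasons[ok & tag_at <= blen] <- "no_barcode"
  ok <- ok & tag_at > blen

  flank_start <- tag_at + nchar(tag)
  flank_len <- nchar(reads) - flank_start + 1L
  reasons[ok & flank_len < k] <- "short_flank"
  ok <- ok & flank_len >= k

  barcode <- substring(reads, tag_at - blen, tag_at - 1L)
  fl <- substring(reads, flank_start, flank_start + k - 1L)

  # exact unique placement via a k-mer index over both strands
  L <- nchar(seqn)
  idx_pos <- seq_len(L - k + 1L)
  kmers <- substring(seqn, idx_pos, idx_pos + k - 1L)
  kmers_rc <- substring(revcomp(seqn), idx_pos, idx_pos + k - 1L)
  all_k <- c(kmers, kmers_rc)
  ukm <- unique(all_k)
  occ <- tabulate(match(all_k, ukm), nbins = length(ukm))

  n_occ <- occ[match(fl, ukm)]
  reasons[ok & is.na(n_occ)] <- "unmapped"
  reasons[ok & !is.na(n_occ) & n_occ > 1] <- "multi_mapped"
  ok <- ok & !is.na(n_occ) & n_occ == 1

  i_fwd <- match(fl[ok], kmers)
  i_rev <- match(fl[ok], kmers_rc)
  strand <- ifelse(!is.na(i_fwd), "+", "-")
  pos <- ifelse(!is.na(i_fwd), i_fwd - 1L, L - i_rev)

  obs <- data.frame(barcode = barcode[ok], position = as.integer(pos),
                    strand = strand, stringsAsFactors = FALSE)
  rej <- table(reasons[!ok])
  list(observations = obs,
       rejected = stats::setNames(as.integer(rej), names(rej)))
}

#' Build the insertion pool from mapped observations
#'
#' A barcode is retained at its modal (position, strand) location when that
#' location holds at least `min_frac` of the barcode's reads and has at least
#' `min_reads` supporting reads; otherwise the barcode is dropped as
#' ambiguous or chimeric. Retained barcodes are annotated against the gene
#' model when one is supplied.
#'
#' @param observations data.frame from [map_insertions()].
#' @param genes optional gene table for [assign_gene()] annotation.
#' @param min_reads minimum reads at the modal location (default 2).
#' @param min_frac minimum fraction of the barcode's reads at the modal
#'   location (default 0.75).
#' @return data.frame (the InsertionPool): barcode, position, strand,
#'   n_reads, and, when annotated, locus_tag, rel_pos, central.
#' @export
design_pool <- function(observations, genes = NULL,
                        min_reads = 2L, min_frac = 0.75) {
  if (nrow(observations) == 0) {
    pool <- data.frame(barcode = character(), position = integer(),
                       strand = character(), n_reads = integer(),
                       stringsAsFactors = FALSE)
  } else {
    key <- paste(observations$barcode, observations$position,
                 observations$strand, sep = "\r")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    locs <- data.frame(barcode = parts[, 1],
                       position = as.integer(parts[, 2]),
                       strand = parts[, 3],
                       n_reads = as.integer(tab),
                       stringsAsFactors = FALSE)
    # modal location per barcode (deterministic tie-break, ties always fail
    # the 75% rule when there are exactly two locations anyway)
    locs <- locs[order(locs$barcode, -locs$n_reads,
                       locs$position, locs$strand), ]
    total <- stats::ave(locs$n_reads, locs$barcode, FUN = sum)
    first <- !duplicated(locs$barcode)
    keep <- first & locs$n_reads >= min_reads &
      locs$n_reads / total >= min_frac
    pool <- locs[keep, , drop = FALSE]
    rownames(pool) <- NULL
  }
  if (!is.null(genes) && nrow(pool) > 0)
    pool <- cbind(pool, assign_gene(pool$position, pool$strand, genes))
  pool
}

#' Summary statistics of an insertion pool
#'
#' Tabulates the pool the way RB-TnSeq libraries are characterized: total
#' retained insertions, central insertions (relative position within
#' [0.1, 0.9] of a gene), distinct insertion locations, genes carrying at
#' least one central insertion, mean insertion mutants per represented gene,
#' and the expectation under uniform insertion: `floor(coding_fraction *
#' total)` insertions in genes, 80% of which are expected central.
#'
#' @param pool annotated InsertionPool from [design_pool()].
#' @param genes gene table (defines the protein-coding gene universe).
#' @param coding_fraction protein-coding fraction of the genome used for the
#'   expectation (default 0.85).
#' @return named list of statistics (LibraryStats).
#' @export
library_stats <- function(pool, genes, coding_fraction = 0.85) {
  stopifnot(!is.null(pool$central))
  total <- nrow(pool)
  central <- sum(pool$central)
  distinct_loc <- nrow(unique(pool[, c("position", "strand")]))
  central_genes <- unique(pool$locus_tag[pool$central])
  n_genes_central <- length(central_genes)
  mean_mutants <- if (n_genes_central > 0) central / n_genes_central else NA_real_
  list(total_insertions = total,
       central_insertions = central,
       distinct_locations = distinct_loc,
       genes_with_central = n_genes_central,
       frac_genes_with_central = n_genes_central / nrow(genes),
       mean_mutants_per_gene = mean_mutants,
       expected_in_gene = expected_in_gene(total, coding_fraction),
       expected_central = 0.8 * expected_in_gene(total, coding_fraction))
}

#' Expected in-gene insertions under uniform placement
#'
#' @param total total mapped insertions.
#' @param coding_fraction protein-coding fraction of the genome.
#' @return `floor(coding_fraction * total)`.
#' @export
expected_in_gene <- function(total, coding_fraction = 0.85) {
  floor(coding_fraction * total)
}
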