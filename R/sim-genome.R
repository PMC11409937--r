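#' Simulate a bacterial genome with a packed gene annotation
#'
#' Generates a random nucleotide sequence and places `n_genes` non-overlapping
#' genes on both strands so that the total gene span is within 1% of
#' `coding_fraction * genome_length` (~85% of a bacterial genome is
#' protein-coding, which is the default here). Gene lengths are drawn around
#' their common mean and rescaled to hit the target coding span exactly up to
#' rounding; intergenic gaps are apportioned randomly.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer overriding `cfg$seed`.
#' @return list with `sequence` (single character string), `genes`
#'   (data.frame: locus_tag, start, end, strand, length, midpoint; 1-based
#'   inclusive coordinates), and `seqname`.
#' @export
simulate_genome <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  L <- cfg$genome_length
  n <- cfg$n_genes
  target <- round(cfg$coding_fraction * L)
  if (target < n * 30)
    stop("infeasible gene packing: coding target smaller than minimal gene lengths")

  mean_len <- target / n
  lens <- pmax(30L, round(stats::rnorm(n, mean_len, 0.15 * mean_len)))
  lens <- pmax(30L, round(lens * target / sum(lens)))
  # absorb rounding residue in the last gene
  lens[n] <- lens[n] + (target - sum(lens))
  if (lens[n] < 30) stop("infeasible gene packing: residual gene too short")

  intergenic <- L - sum(lens)
  if (intergenic < 0) stop("infeasible gene packing: genes exceed genome length")
  gap_w <- stats::rexp(n + 1)
  gaps <- floor(gap_w / sum(gap_w) * intergenic)
  gaps[n + 1] <- gaps[n + 1] + (intergenic - sum(gaps))

  starts <- cumsum(c(1L, lens[-n] + gaps[2:n])) + gaps[1]
  ends <- starts + lens - 1L
  stopifnot(ends[n] <= L)

  genes <- data.frame(
    locus_tag = sprintf("g%04d", seq_len(n)),
    start = as.integer(starts),
    end = as.integer(ends),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  genes$length <- genes$end - genes$start + 1L
  genes$midpoint <- (genes$start + genes$end) / 2

  seqn <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  list(sequence = seqn, genes = genes, seqname = "chr1")
}

#' Reverse-complement a nucleotide string
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
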