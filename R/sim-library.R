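#' Generate unique random barcodes
#'
#' @param n number of barcodes.
#' @param width barcode length in bp.
#' @param max_attempts regeneration rounds before giving up on uniqueness.
#' @return character vector of `n` distinct barcodes.
#' @export
random_barcodes <- function(n, width = 20L, max_attempts = 10L) {
  if (4^width < 2 * n)
    stop("barcode space too small for ", n, " unique barcodes of width ", width)
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  bc <- unique(draw(n))
  attempts <- 0L
  while (length(bc) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("barcode collision rate too high; could not generate unique barcodes")
    bc <- unique(c(bc, draw(n - length(bc))))
  }
  bc[seq_len(n)]
}

#' Simulate a barcoded Tn5 insertion library and its mapping reads
#'
#' Insertion positions are uniform over the genome (kept `flank_length` bp
#' away from the ends so every junction has a full genomic flank). Each
#' insertion carries a unique random barcode. A configurable fraction of
#' chimeric barcodes is emitted at a second location, and a configurable
#' fraction of junction-free junk reads is injected, both for negative
#' testing of the mapping stage.
#'
#' Mapping reads follow the [tn_layout()]:
#' `barcode | junction tag | genomic flank`. For a `+` insertion at 0-based
#' position p the flank is the forward-strand sequence starting at p; for a
#' `-` insertion it is the reverse complement of the sequence ending at p.
#'
#' @param genome output of [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param layout a [tn_layout()].
#' @param flank_length genomic flank length emitted per read.
#' @param seed optional integer overriding `cfg$seed`.
#' @return list with `pool` (truth table: barcode, position (0-based junction
#'   coordinate), strand, chimeric flag, plus gene annotation columns from
#'   [assign_gene()]) and `reads` (named character vector of mapping reads).
#' @export
simulate_library <- function(genome, cfg, layout = tn_layout(),
                             flank_length = 30L, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed + 1L)
  L <- nchar(genome$sequence)
  n <- cfg$n_insertions
  margin <- flank_length + 1L
  pos <- sample.int(L - 2L * margin, n, replace = TRUE) + margin  # 0-based
  strand <- sample(c("+", "-"), n, replace = TRUE)
  bc <- random_barcodes(n, cfg$barcode_length)

  pool <- data.frame(barcode = bc, position = as.integer(pos),
                     strand = strand, chimeric = FALSE,
                     stringsAsFactors = FALSE)

  n_chim <- floor(cfg$chimera_fraction * n)
  if (n_chim > 0) {
    idx <- sample.int(n, n_chim)
    pos2 <- sample.int(L - 2L * margin, n_chim, replace = TRUE) + margin
    extra <- data.frame(barcode = bc[idx], position = as.integer(pos2),
                        strand = sample(c("+", "-"), n_chim, replace = TRUE),
                        chimeric = TRUE, stringsAsFactors = FALSE)
    pool$chimeric[idx] <- TRUE
    pool <- rbind(pool, extra)
  }

  ann <- assign_gene(pool$position, pool$strand, genome$genes)
  pool <- cbind(pool, ann)

  flank <- junction_flank(genome$sequence, pool$position, pool$strand,
                          flank_length)
  reads <- paste0(rep(pool$barcode, each = cfg$reads_per_insertion),
                  layout$junction_tag,
                  rep(flank, each = cfg$reads_per_insertion))
  names(reads) <- sprintf("map_%06d", seq_along(reads))

  n_junk <- floor(cfg$junk_read_fraction * length(reads))
  if (n_junk > 0) {
    junk <- vapply(seq_len(n_junk), function(i)
      paste(sample(c("A", "C", "G", "T"), nchar(reads[[1]]), replace = TRUE),
            collapse = ""), character(1))
    names(junk) <- sprintf("junk_%06d", seq_len(n_junk))
    reads <- c(reads, junk)
  }
  list(pool = pool, reads = reads)
}

#' Genomic flank sequence at a junction coordinate
#'
#' @param sequence genome string.
#' @param position 0-based junction coordinates.
#' @param strand "+" or "-" per position.
#' @param width flank width in bp.
#' @return character vector of strand-oriented flanks.
#' @keywords internal
junction_flank <- function(sequence, position, strand, width) {
  fwd <- substring(sequence, position + 1L, position + width)
  rev_raw <- substring(sequence, position - width + 2L, position + 1L)
  out <- ifelse(strand == "+", fwd, NA_character_)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(rev_raw[neg])
  out
}
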