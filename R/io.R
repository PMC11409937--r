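#' Read and write the pipeline's standard file formats
#'
#' Genome FASTA and gene GFF3 go through Biostrings and rtracklayer; FASTQ
#' through Biostrings (Phred+33, constant quality on write since the
#' pipeline is quality-agnostic); tables are plain TSV with headers.
#'
#' @param x object to write (see individual functions).
#' @param path file path.
#' @name barseqfit-io
NULL

#' @describeIn barseqfit-io write a genome list (from [simulate_genome()])
#'   to FASTA.
#' @export
write_genome <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(x$sequence, x$seqname))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @describeIn barseqfit-io read a single-sequence genome FASTA into a
#'   genome list (without annotation).
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1)
    stop("expected a single-contig genome FASTA")
  list(sequence = as.character(seqs[[1]]), genes = NULL,
       seqname = sub("\\s.*$", "", names(seqs)[1]))
}

#' @describeIn barseqfit-io write a gene table to GFF3 (1-based inclusive).
#' @param seqname contig name for GFF output.
#' @export
write_annotation <- function(x, path, seqname = "chr1") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = x$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- x$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- x$locus_tag
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @describeIn barseqfit-io read a GFF3 gene annotation into a gene table.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- data.frame(
    locus_tag = if (!is.null(gr$locus_tag)) gr$locus_tag else gr$ID,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes$length <- genes$end - genes$start + 1L
  genes$midpoint <- (genes$start + genes$end) / 2
  genes
}

#' @describeIn barseqfit-io write reads (character vector, named or not) to
#'   FASTQ.
#' @export
write_fastq <- function(x, path) {
  if (length(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  nm <- if (!is.null(names(x))) names(x) else sprintf("read_%06d", seq_along(x))
  seqs <- Biostrings::DNAStringSet(stats::setNames(as.character(x), nm))
  Biostrings::writeXStringSet(seqs, path, format = "fastq")
  invisible(path)
}

#' @describeIn barseqfit-io read FASTQ sequences into a named character
#'   vector. Malformed records raise an error.
#' @export
read_fastq <- function(path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                   error = function(e)
                     stop("malformed FASTQ at ", path, ": ",
                          conditionMessage(e)))
  stats::setNames(as.character(seqs), names(seqs))
}

#' @describeIn barseqfit-io write any data.frame as TSV with header.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn barseqfit-io read a TSV with header.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @describeIn barseqfit-io write a `barcode_counts` or `filtered_counts`
#'   object's matrix as TSV (barcode column + one column per sample).
#' @export
write_counts <- function(x, path) {
  m <- if (is.list(x)) x$counts else x
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @describeIn barseqfit-io read a counts TSV back into an integer matrix.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  m
}
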