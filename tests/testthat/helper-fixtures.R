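# Deterministic toy fixtures shared across test files.

toy_barcodes <- function(n) {
  stopifnot(n <= 64)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i)
    paste0(strrep(bases[i %% 4 + 1], 7),
           strrep(bases[(i %/% 4) %% 4 + 1], 7),
           strrep(bases[(i %/% 16) %% 4 + 1], 6)), character(1))
}

# A 12-barcode count matrix + pool exercising every count-filter rule once;
# survivors were determined by hand-applying the three rules (unknown,
# T0 < 3, gene < 30 T0 reads) plus the central-insertion restriction.
toy_filter_fixture <- function() {
  bcs <- toy_barcodes(12)
  pool <- data.frame(
    barcode = bcs[1:11],   # bc12 stays unknown
    position = 1:11, strand = "+",
    locus_tag = c("gA", "gA", "gA", "gB", "gB", "gB", "gC", "gC", NA, "gD",
                  "gD"),
    rel_pos = c(0.5, 0.4, 0.6, 0.5, 0.5, 0.5, 0.3, 0.7, NA, 0.05, 0.5),
    central = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                FALSE, TRUE),
    stringsAsFactors = FALSE)
  t0 <- c(20L, 15L, 2L, 3L, 3L, 24L, 10L, 19L, 50L, 40L, 25L)
  d3 <- rep(10L, 11)
  counts <- rbind(cbind(T0 = t0, s1 = d3),
                  matrix(c(30L, 10L), nrow = 1,
                         dimnames = list(NULL, c("T0", "s1"))))
  rownames(counts) <- bcs
  sheet <- data.frame(sample = c("T0", "s1"), condition = c("T0", "alone"),
                      replicate = c(0L, 1L), timepoint = c("T0", "day3"),
                      stringsAsFactors = FALSE)
  bc <- structure(list(counts = counts, known = bcs %in% pool$barcode,
                       sample_sheet = sheet), class = "barcode_counts")
  list(bc = bc, pool = pool, bcs = bcs)
}
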