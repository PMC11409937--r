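make_read <- function(barcode, flank, layout = tn_layout()) {
  paste0(barcode, layout$junction_tag, flank)
}

test_that("error-free simulated reads map back to their true position and strand", {
  cfg <- tiny_config(seed = 13L)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  mp <- map_insertions(lib$reads, g)
  expect_length(mp$rejected, 0)
  key_true <- paste(lib$pool$barcode, lib$pool$position, lib$pool$strand)
  key_obs <- unique(paste(mp$observations$barcode, mp$observations$position,
                          mp$observations$strand))
  expect_true(all(key_true %in% key_obs))
  expect_true(all(key_obs %in% key_true))
})

test_that("reads are discarded with the correct tallied reasons", {
  genome <- list(sequence = paste(rep("ACGT", 500), collapse = ""),
                 seqname = "chr1")
  # build a genome with distinctive unique 20-mers to map against
  set.seed(99)
  genome$sequence <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                           collapse = "")
  lay <- tn_layout()
  bc <- strrep("A", 20)
  good_flank <- substring(genome$sequence, 101, 130)
  reads <- c(
    good = make_read(bc, good_flank),
    nojunc = paste0(bc, "TTTTTTTTTTTTTTTTTTT", good_flank),
    nobarcode = paste0("ACGT", lay$junction_tag, good_flank),
    shortflank = make_read(bc, substring(good_flank, 1, 10)),
    unmapped = make_read(bc, strrep("AC", 15)))
  # make the "unmapped" flank truly absent
  expect_equal(oracle_flank_hits(strrep("AC", 10), genome$sequence), 0)
  mp <- map_insertions(reads, genome, lay)
  expect_equal(nrow(mp$observations), 1)
  expect_equal(mp$observations$position, 100)  # 0-based
  expect_equal(mp$observations$strand, "+")
  expect_equal(mp$rejected[["no_junction"]], 1L)
  expect_equal(mp$rejected[["no_barcode"]], 1L)
  expect_equal(mp$rejected[["short_flank"]], 1L)
  expect_equal(mp$rejected[["unmapped"]], 1L)
})

test_that("flanks at two genomic sites are discarded as multi-mapped", {
  set.seed(7)
  core <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  repeat_unit <- substring(core, 501, 540)
  genome <- list(sequence = paste0(core, repeat_unit), seqname = "chr1")
  flank <- substring(repeat_unit, 1, 30)
  expect_equal(oracle_flank_hits(substring(flank, 1, 20), genome$sequence), 2)
  mp <- map_insertions(make_read(strrep("C", 20), flank), genome)
  expect_equal(nrow(mp$observations), 0)
  expect_equal(mp$rejected[["multi_mapped"]], 1L)
})

test_that("reverse-strand reads map to the junction coordinate of their flank", {
  set.seed(31)
  seqn <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  genome <- list(sequence = seqn, seqname = "chr1")
  p <- 1500L  # 0-based junction coordinate
  flank <- revcomp(substring(seqn, p - 30 + 2, p + 1))
  mp <- map_insertions(make_read(strrep("G", 20), flank), genome)
  expect_equal(mp$observations$position, p)
  expect_equal(mp$observations$strand, "-")
})

test_that("empty read sets warn and mapping validates the genome alphabet", {
  genome <- list(sequence = strrep("ACGT", 100), seqname = "chr1")
  expect_warning(mp <- map_insertions(character(), genome), "empty")
  expect_equal(nrow(mp$observations), 0)
  expect_error(map_insertions("ACGT", list(sequence = "ACGTN")), "alphabet")
})

test_that("pool design applies the modal-share and support rules", {
  obs1 <- data.frame(barcode = "b1", position = rep(10L, 10), strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(design_pool(obs1)$position, 10L)
  # 50/50 tie fails the 75% modal-share rule
  obs2 <- data.frame(barcode = "b2", position = rep(c(10L, 99L), each = 5),
                     strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(design_pool(obs2)), 0)
  # a single read fails the >= 2 support rule
  obs3 <- data.frame(barcode = "b3", position = 5L, strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(design_pool(obs3)), 0)
})

test_that("pool design matches exhaustive rule application on a mixed set", {
  set.seed(17)
  obs <- do.call(rbind, lapply(sprintf("bc%02d", 1:20), function(b) {
    n_loc <- sample(1:3, 1)
    locs <- sample(1000L, n_loc)
    data.frame(barcode = b,
               position = rep(locs, sample(1:8, n_loc, replace = TRUE)),
               strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }))
  got <- design_pool(obs)
  got <- got[order(got$barcode), c("barcode", "position", "strand", "n_reads")]
  rownames(got) <- NULL
  want <- oracle_pool_rule(obs)
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("adding reads at the modal location never drops a retained barcode", {
  set.seed(23)
  for (i in 1:20) {
    n_loc <- sample(1:3, 1)
    obs <- data.frame(barcode = "b",
                      position = rep(sample(100L, n_loc),
                                     sample(2:6, n_loc, replace = TRUE)),
                      strand = "+", stringsAsFactors = FALSE)
    before <- design_pool(obs)
    if (nrow(before) == 1) {
      extra <- data.frame(barcode = "b", position = before$position,
                          strand = before$strand, stringsAsFactors = FALSE)
      after <- design_pool(rbind(obs, extra[rep(1, 3), ]))
      expect_equal(nrow(after), 1)
      expect_equal(after$position, before$position)
    }
  }
})

test_that("gene assignment computes strand-aware relative positions", {
  genes <- data.frame(locus_tag = c("fwd", "rev"),
                      start = c(1001L, 5001L), end = c(2000L, 6000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  # forward gene, offset 500 -> rel 0.5, central
  a <- assign_gene(1000L + 500L, "+", genes)  # 0-based position
  expect_equal(a$rel_pos, 0.5)
  expect_true(a$central)
  # forward gene, offset 50 -> rel 0.05, not central
  b <- assign_gene(1000L + 50L, "+", genes)
  expect_equal(b$rel_pos, 0.05)
  expect_false(b$central)
  # reverse gene, genomic offset 50 from the chromosome-left end -> rel 0.95
  # on the coding strand, not central
  c_ <- assign_gene(5000L + 50L, "+", genes)
  expect_equal(c_$rel_pos, 0.95)
  expect_false(c_$central)
  # boundaries inclusive: rel exactly 0.1 and 0.9 are central
  d <- assign_gene(c(1000L + 100L, 1000L + 900L), c("+", "+"), genes)
  expect_equal(d$rel_pos, c(0.1, 0.9))
  expect_true(all(d$central))
  # intergenic position
  e <- assign_gene(100L, "+", genes)
  expect_true(is.na(e$locus_tag))
  expect_error(assign_gene(-5L, "+", genes), "non-negative")
})

test_that("library stats reproduce the expected-insertion arithmetic", {
  expect_equal(expected_in_gene(165694, 0.85), 140839)
  cfg <- tiny_config(seed = 19L)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  stats <- library_stats(lib$pool, g$genes, cfg$coding_fraction)
  # stats equal direct tabulation of the truth pool
  expect_equal(stats$total_insertions, nrow(lib$pool))
  expect_equal(stats$central_insertions, sum(lib$pool$central))
  expect_equal(stats$distinct_locations,
               nrow(unique(lib$pool[, c("position", "strand")])))
  expect_equal(stats$genes_with_central,
               length(unique(lib$pool$locus_tag[lib$pool$central])))
  expect_equal(stats$mean_mutants_per_gene,
               stats$central_insertions / stats$genes_with_central)
  expect_equal(stats$expected_in_gene,
               floor(0.85 * stats$total_insertions))
  expect_equal(stats$expected_central, 0.8 * stats$expected_in_gene)
  expect_lte(stats$central_insertions, stats$total_insertions)
  expect_lte(stats$frac_genes_with_central, 1)
})
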