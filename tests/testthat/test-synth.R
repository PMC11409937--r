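test_that("simulated genome packs genes to the target coding fraction", {
  cfg <- sim_config(genome_length = 200000L, n_genes = 150L,
                    coding_fraction = 0.85, seed = 5L)
  g <- simulate_genome(cfg)
  span <- sum(g$genes$length)
  expect_gte(span, 168300)
  expect_lte(span, 171700)
  expect_equal(nrow(g$genes), 150)
  # genes are non-overlapping and inside the genome
  o <- g$genes[order(g$genes$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))
  expect_true(all(o$start >= 1) && all(o$end <= cfg$genome_length))
})

test_that("degenerate packing places a single gene spanning the coding target", {
  cfg <- sim_config(genome_length = 10000L, n_genes = 1L,
                    coding_fraction = 0.5, n_insertions = 10L, seed = 2L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 1)
  expect_equal(g$genes$length, 5000)
})

test_that("infeasible gene packing raises a configuration error", {
  expect_error(sim_config(genome_length = 1000L, n_genes = 100L,
                          coding_fraction = 0.5),
               "infeasible")
})

test_that("identical config and seed give byte-identical FASTA and GFF", {
  cfg <- tiny_config(seed = 42L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    g <- simulate_genome(cfg)
    write_genome(g, file.path(d, "genome.fasta"))
    write_annotation(g$genes, file.path(d, "genes.gff3"), g$seqname)
  }
  expect_identical(readLines(file.path(d1, "genome.fasta")),
                   readLines(file.path(d2, "genome.fasta")))
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))
})

test_that("genome and annotation round-trip through the package readers", {
  cfg <- tiny_config(seed = 8L)
  g <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_genome(g, file.path(d, "g.fasta"))
  write_annotation(g$genes, file.path(d, "g.gff3"), g$seqname)
  g2 <- read_genome(file.path(d, "g.fasta"))
  a2 <- read_annotation(file.path(d, "g.gff3"))
  expect_identical(g2$sequence, g$sequence)
  expect_equal(a2[c("locus_tag", "start", "end", "strand")],
               g$genes[c("locus_tag", "start", "end", "strand")])
})

test_that("insertions fall in genes at about the coding fraction", {
  cfg <- sim_config(genome_length = 100000L, n_genes = 80L,
                    n_insertions = 10000L, read_depth_per_sample = 1000L,
                    seed = 3L)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  in_gene <- sum(!is.na(lib$pool$locus_tag))
  # binomial(10000, ~0.85): allow 4 sd
  expect_gt(in_gene, 8500 - 4 * sqrt(10000 * 0.85 * 0.15))
  expect_lt(in_gene, 8500 + 4 * sqrt(10000 * 0.85 * 0.15))
})

test_that("chimeric barcode counts equal the generator's committed draw", {
  cfg <- sim_config(genome_length = 50000L, n_genes = 30L,
                    n_insertions = 2000L, chimera_fraction = 0.05,
                    read_depth_per_sample = 1000L, seed = 9L)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  # enumerate the emitted pool: chimeric barcodes appear at two locations
  dup <- table(lib$pool$barcode)
  expect_equal(sum(dup == 2), floor(0.05 * 2000))
  expect_equal(sum(lib$pool$chimeric), 2 * floor(0.05 * 2000))
  # chimera_fraction = 0 leaves every barcode at exactly one location
  cfg0 <- sim_config(genome_length = 50000L, n_genes = 30L,
                     n_insertions = 500L, read_depth_per_sample = 1000L,
                     seed = 9L)
  lib0 <- simulate_library(simulate_genome(cfg0), cfg0)
  expect_true(all(table(lib0$pool$barcode) == 1))
})

test_that("selection reproduces the closed-form expected abundances", {
  # 3 strains in 3 genes with planted effects {-2, 0, +1}: expected day-3
  # counts follow depth * normalize(a0 * 2^f); check the multinomial mean
  # over 200 replicate draws against that expectation within 3 s.e.
  cfg <- sim_config(genome_length = 6000L, n_genes = 3L, n_insertions = 3L,
                    coding_fraction = 0.6,
                    conditions = "phage", has_phage = TRUE, has_fungi = FALSE,
                    n_replicates = 200L, read_depth_per_sample = 5000L,
                    seed = 21L)
  g <- simulate_genome(cfg)
  # place one strain centrally in each gene
  pool <- data.frame(
    barcode = random_barcodes(3, 20),
    position = as.integer(round(g$genes$midpoint)), strand = "+",
    chimeric = FALSE, stringsAsFactors = FALSE)
  pool <- cbind(pool, assign_gene(pool$position, pool$strand, g$genes))
  eff <- list(effects = matrix(c(-2, 0, 1), nrow = 3,
                               dimnames = list(g$genes$locus_tag, "phage")))
  counts <- simulate_selection(pool, eff, cfg)
  p0 <- counts$true_freq0
  p3 <- p0 * 2^c(-2, 0, 1)
  p3 <- p3 / sum(p3)
  expected <- 5000 * p3
  day3 <- counts$counts[, counts$sample_sheet$timepoint != "T0"]
  mean_counts <- rowMeans(day3)
  se <- sqrt(5000 * p3 * (1 - p3) / 200)
  expect_true(all(abs(mean_counts - expected) < 3 * se))
})

test_that("neutral selection leaves expected abundances at T0 frequencies", {
  cfg <- tiny_config(seed = 4L)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  eff <- simulate_effects(g$genes, cfg, n_antagonistic = 0L,
                          n_phage_benefit = 0L, n_fungus_cost = 0L,
                          n_deleterious = 0L)
  counts <- simulate_selection(lib$pool, eff, cfg)
  p0 <- counts$true_freq0
  day3 <- counts$counts[, counts$sample_sheet$timepoint != "T0", drop = FALSE]
  # pooled day-3 frequencies match inoculum frequencies (f = 0 fixed point)
  phat <- rowSums(day3) / sum(day3)
  expect_lt(max(abs(phat - p0)), 6 * sqrt(max(p0) / sum(day3)))
})

test_that("default planted effects keep a neutral majority and the planted signs", {
  cfg <- sim_config(seed = 1L)
  g <- simulate_genome(cfg)
  eff <- simulate_effects(g$genes, cfg)
  cls <- eff$classes$class
  expect_gte(mean(cls == "neutral"), 0.8)
  expect_true(all(eff$effects[cls == "neutral", ] == 0))
  comp <- condition_composition(cfg)
  ant <- eff$effects[cls == "antagonistic-pleiotropic", , drop = FALSE]
  phage_conds <- comp$condition[comp$has_phage]
  fungi_only <- comp$condition[comp$has_fungi & !comp$has_phage]
  expect_true(all(ant[, phage_conds] > 0))
  expect_true(all(ant[, fungi_only] < 0))
})

test_that("BarSeq read emission reproduces the count matrix at error rate 0", {
  counts <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 3,
                   dimnames = list(c("AAAAAAAAAAAAAAAAAAAA",
                                     "CCCCCCCCCCCCCCCCCCCC",
                                     "GGGGGGGGGGGGGGGGGGGG"),
                                   c("s1", "s2")))
  reads <- simulate_barseq_reads(counts, seed = 2L)
  expect_length(reads$s1, 7)   # conservation: column sum
  expect_length(reads$s2, 8)
  for (s in c("s1", "s2")) {
    tl <- extract_barcodes(reads[[s]])
    expect_equal(tl$n_rejected, 0L)
    v <- counts[, s][counts[, s] > 0]
    expect_equal(tl$tally[names(v)], v)
  }
})

test_that("BarSeq base errors equal the generator's committed draw", {
  counts <- matrix(500L, nrow = 1,
                   dimnames = list("ACGTACGTACGTACGTACGT", "s1"))
  reads <- simulate_barseq_reads(counts, error_rate = 0.01, seed = 6L)
  truth <- paste0(barseq_layout()$left_flank, "ACGTACGTACGTACGTACGT",
                  barseq_layout()$right_flank)
  n_bad_bases <- sum(vapply(reads$s1, hamming, integer(1), b = truth))
  expect_equal(n_bad_bases, attr(reads$s1, "n_errors"))
  expect_gt(n_bad_bases, 0)
})

test_that("growth assay counts are Poisson around titer * volume * dilution", {
  sc <- data.frame(condition = "alone", day = 1, unit = "cfu", titer = 1e9)
  obs <- simulate_growth_assay(sc, n_bio = 30L, n_tech = 10L, seed = 3L)
  expect_true(all(obs$dilution == 1e-6))     # targets ~100 counts
  lambda <- 1e9 * 0.1 * 1e-6
  expect_lt(abs(mean(obs$count) - lambda), 4 * sqrt(lambda / nrow(obs)))
  # titer 0 gives all-zero counts
  obs0 <- simulate_growth_assay(
    data.frame(condition = "x", day = 3, unit = "cfu", titer = 0), seed = 1L)
  expect_true(all(obs0$count == 0))
  expect_error(simulate_growth_assay(
    data.frame(condition = "x", day = 1, unit = "cfu", titer = -1)),
    "negative")
})
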