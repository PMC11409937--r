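# Independent brute-force oracles used to cross-check the pipeline's
# normalizations, pool-design rule, set enumeration and flank mapping.
# Deliberately plain, loop-based implementations.

oracle_running_median <- function(f, midpoint, window) {
  n <- length(f)
  w <- min(window, n)
  if (w %% 2 == 0) w <- w - 1
  h <- (w - 1) / 2
  ord <- order(midpoint)
  fo <- f[ord]
  res <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (d in -h:h) {
      j <- i + d
      while (j < 1) j <- j + n
      while (j > n) j <- j - n
      vals <- c(vals, fo[j])
    }
    s <- sort(vals)
    m <- length(s)
    med <- if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
    res[i] <- fo[i] - med
  }
  out <- f
  out[ord] <- res
  out
}

# Exhaustive scan of histogram-bin centers (multiples of bin_width) counting
# points within half a bin width; inputs must avoid exact bin boundaries.
oracle_mode <- function(f, bin_width = 0.05) {
  qs <- quantile(f, c(0.025, 0.975), names = FALSE, type = 7)
  sel <- f[f >= qs[1] & f <= qs[2]]
  ks <- seq(floor(min(sel) / bin_width), ceiling(max(sel) / bin_width))
  centers <- ks * bin_width
  counts <- vapply(centers, function(cc) sum(abs(sel - cc) <= bin_width / 2),
                   integer(1))
  best <- centers[counts == max(counts)]
  best[order(abs(best), best)][1]
}

oracle_pool_rule <- function(observations, min_reads = 2, min_frac = 0.75) {
  kept <- list()
  for (b in unique(observations$barcode)) {
    sub <- observations[observations$barcode == b, ]
    loc <- paste(sub$position, sub$strand)
    tab <- sort(table(loc), decreasing = TRUE)
    if (tab[1] >= min_reads && tab[1] / nrow(sub) >= min_frac) {
      parts <- strsplit(names(tab)[1], " ")[[1]]
      kept[[b]] <- data.frame(barcode = b,
                              position = as.integer(parts[1]),
                              strand = parts[2],
                              n_reads = as.integer(tab[1]),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(kept) == 0) return(NULL)
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out[order(out$barcode), ]
}

# Exhaustive power-set membership counts over named per-condition gene sets.
oracle_membership <- function(sets) {
  conds <- names(sets)
  genes <- unique(unlist(sets))
  subsets <- unlist(lapply(seq_along(conds), function(d)
    combn(conds, d, simplify = FALSE)), recursive = FALSE)
  res <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    count = vapply(subsets, function(ss) {
      sum(vapply(genes, function(g) {
        inn <- vapply(conds, function(cn) g %in% sets[[cn]], logical(1))
        all(inn[conds %in% ss]) && !any(inn[!conds %in% ss])
      }, logical(1)))
    }, integer(1)), stringsAsFactors = FALSE)
  res
}

# Occurrences of a flank (either orientation) in a genome by plain substring
# scan.
oracle_flank_hits <- function(flank, genome_seq) {
  hits <- function(pat) {
    g <- gregexpr(pat, genome_seq, fixed = TRUE)[[1]]
    if (g[1] == -1) 0L else length(g)
  }
  hits(flank) + hits(revcomp(flank))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Small config used across tests: tiny genome so mapping stays fast.
tiny_config <- function(seed = 11L, ...) {
  sim_config(genome_length = 20000L, n_genes = 20L, n_insertions = 400L,
             read_depth_per_sample = 20000L, seed = seed, ...)
}
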