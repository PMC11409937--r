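#' Strong-effect gene sets per condition
#'
#' @param fitness_table FitnessTable from [aggregate_replicates()].
#' @return named list (per condition) of data.frames with locus_tag and
#'   effect for strong genes.
#' @export
strong_sets <- function(fitness_table) {
  ft <- fitness_table[fitness_table$strong, , drop = FALSE]
  conds <- unique(fitness_table$condition)
  out <- lapply(conds, function(cn)
    ft[ft$condition == cn, c("locus_tag", "effect"), drop = FALSE])
  names(out) <- conds
  out
}

#' Condition-combination membership counts (UpSet semantics)
#'
#' For every nonempty subset of conditions, counts the genes that are strong
#' in exactly that subset. Counts sum to the size of the union of strong
#' sets.
#'
#' @param fitness_table FitnessTable from [aggregate_replicates()].
#' @return data.frame: subset (condition labels joined by "+"), degree
#'   (subset size), count; one row per nonempty subset, zeros included.
#' @export
membership_counts <- function(fitness_table) {
  conds <- unique(fitness_table$condition)
  stopifnot(length(conds) >= 1)
  sets <- strong_sets(fitness_table)
  genes <- unique(unlist(lapply(sets, function(s) s$locus_tag),
                         use.names = FALSE))
  member <- vapply(conds, function(cn) genes %in% sets[[cn]]$locus_tag,
                   logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, conds))
  key_of <- function(v) paste(conds[v], collapse = "+")
  gene_key <- apply(member, 1, key_of)

  subsets <- unlist(lapply(seq_along(conds), function(d)
    utils::combn(conds, d, simplify = FALSE)), recursive = FALSE)
  out <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    degree = lengths(subsets), stringsAsFactors = FALSE)
  tab <- table(gene_key)
  out$count <- as.integer(tab[out$subset])
  out$count[is.na(out$count)] <- 0L
  out
}

#' Classify cross-condition pleiotropy of strong-effect genes
#'
#' A gene is antagonistically pleiotropic when it has a strong positive call
#' in at least one phage-containing condition and a strong negative call in
#' at least one fungi-without-phage condition, or the mirror pattern. Genes
#' strong in two or more conditions with a single sign are concordant
#' (positive/negative); genes strong in exactly one condition are
#' single-condition; everything else is none. Condition composition is taken
#' from an explicit declaration, never inferred from labels.
#'
#' @param fitness_table FitnessTable from [aggregate_replicates()].
#' @param composition data.frame: condition, has_phage, has_fungi (e.g.
#'   [condition_composition()] or distinct sample-sheet rows).
#' @return data.frame per gene strong anywhere: locus_tag, class,
#'   n_strong, plus per-condition fitness/t support in attribute
#'   `"support"`.
#' @export
classify_pleiotropy <- function(fitness_table, composition) {
  stopifnot(all(c("condition", "has_phage", "has_fungi") %in%
                  colnames(composition)))
  st <- fitness_table[fitness_table$strong, , drop = FALSE]
  st <- merge(st, composition, by = "condition", sort = FALSE)
  genes <- sort(unique(st$locus_tag))
  cls <- vapply(genes, function(g) {
    s <- st[st$locus_tag == g, , drop = FALSE]
    pos_phage <- any(s$effect == "positive" & s$has_phage)
    neg_fungi <- any(s$effect == "negative" & s$has_fungi & !s$has_phage)
    neg_phage <- any(s$effect == "negative" & s$has_phage)
    pos_fungi <- any(s$effect == "positive" & s$has_fungi & !s$has_phage)
    if ((pos_phage && neg_fungi) || (neg_phage && pos_fungi))
      return("antagonistic")
    if (nrow(s) >= 2 && all(s$effect == "positive"))
      return("concordant-positive")
    if (nrow(s) >= 2 && all(s$effect == "negative"))
      return("concordant-negative")
    if (nrow(s) == 1) return("single-condition")
    "none"
  }, character(1))
  out <- data.frame(locus_tag = genes, class = unname(cls),
                    n_strong = as.integer(table(st$locus_tag)[genes]),
                    stringsAsFactors = FALSE)
  support <- fitness_table[fitness_table$locus_tag %in% genes,
                           c("locus_tag", "condition", "fitness", "t",
                             "strong", "effect")]
  attr(out, "support") <- support
  out
}

#' Functional-category tallies of strong-effect genes
#'
#' For each condition, computes each category's share of the total
#' annotations carried by that condition's strong genes (a gene contributes
#' once per category it carries), plus the gene-level share (fraction of
#' strong genes carrying the category), since the two tallies differ for
#' multi-annotated genes. Unannotated genes are counted and reported, not
#' silently dropped. Categories present in every condition are flagged.
#'
#' @param fitness_table FitnessTable from [aggregate_replicates()].
#' @param annotation data.frame: locus_tag, category (one row per
#'   gene-category pair; opaque labels, e.g. KEGG BRITE strings).
#' @return data.frame: condition, category, n_annotations, pct_annotations,
#'   n_genes, pct_genes, in_all_conditions; attribute `"unannotated"` maps
#'   condition to its count of unannotated strong genes.
#' @export
category_tally <- function(fitness_table, annotation) {
  stopifnot(all(c("locus_tag", "category") %in% colnames(annotation)))
  sets <- strong_sets(fitness_table)
  rows <- list()
  unann <- integer(0)
  for (cn in names(sets)) {
    genes <- sets[[cn]]$locus_tag
    ann <- annotation[annotation$locus_tag %in% genes, , drop = FALSE]
    unann[cn] <- sum(!genes %in% annotation$locus_tag)
    if (nrow(ann) == 0) next
    n_ann <- table(ann$category)
    n_gene <- table(unique(ann)[, "category"])
    rows[[cn]] <- data.frame(
      condition = cn, category = names(n_ann),
      n_annotations = as.integer(n_ann),
      pct_annotations = 100 * as.integer(n_ann) / nrow(ann),
      n_genes = as.integer(n_gene[names(n_ann)]),
      pct_genes = 100 * as.integer(n_gene[names(n_ann)]) / length(genes),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(condition = character(), category = character(),
                      n_annotations = integer(), pct_annotations = numeric(),
                      n_genes = integer(), pct_genes = numeric(),
                      stringsAsFactors = FALSE)
  shared <- Reduce(intersect, split(out$category, out$condition))
  out$in_all_conditions <- out$category %in% shared
  rownames(out) <- NULL
  attr(out, "unannotated") <- unann
  out
}
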