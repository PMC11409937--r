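#' Titer estimates from dilution-plating observations
#'
#' Each plate gives `count / (dilution * volume)` per ml. Technical
#' replicates are averaged first within each biological replicate; summary
#' statistics (mean, sd) are then computed across biological replicates, so
#' technical replicates are never treated as independent. Plates whose raw
#' count falls outside the countable range [30, 300] are flagged for QC but
#' never excluded. A biological replicate with zero counts on all its plates
#' gets titer 0 and a lower-bound flag.
#'
#' @param obs PlateObservation data.frame (see [simulate_growth_assay()]):
#'   columns condition, day, unit, bio_rep, tech_rep, dilution, volume_ml,
#'   count. A `strain` column, if present, is carried as part of the group
#'   label.
#' @return list with `replicates` (per condition x day x unit x bio_rep:
#'   titer, lower_bound flag, n_flagged_plates outside countable range) and
#'   `summary` (mean_titer, sd_titer, n_bio per condition x day x unit).
#' @export
titer_estimate <- function(obs) {
  stopifnot(all(obs$count >= 0), all(obs$dilution > 0), all(obs$dilution <= 1),
            all(obs$volume_ml > 0))
  label_cols <- intersect(c("strain", "condition", "day", "unit"),
                          colnames(obs))
  obs$per_ml <- obs$count / (obs$dilution * obs$volume_ml)
  obs$flagged <- obs$count < 30 | obs$count > 300

  key_bio <- do.call(paste, c(obs[c(label_cols, "bio_rep")], sep = "\r"))
  first <- !duplicated(key_bio)
  reps <- obs[first, c(label_cols, "bio_rep"), drop = FALSE]
  reps <- reps[order(key_bio[first]), , drop = FALSE]  # align to tapply order
  reps$titer <- as.numeric(tapply(obs$per_ml, key_bio, mean))
  reps$lower_bound <- as.logical(tapply(obs$count, key_bio,
                                        function(x) all(x == 0)))
  reps$n_flagged_plates <- as.integer(tapply(obs$flagged, key_bio, sum))
  rownames(reps) <- NULL

  key_grp <- do.call(paste, c(reps[label_cols], sep = "\r"))
  smry <- reps[!duplicated(key_grp), label_cols, drop = FALSE]
  smry <- smry[order(key_grp[!duplicated(key_grp)]), , drop = FALSE]
  smry$mean_titer <- as.numeric(tapply(reps$titer, key_grp, mean))
  smry$sd_titer <- as.numeric(tapply(reps$titer, key_grp, stats::sd))
  smry$n_bio <- as.integer(tapply(reps$titer, key_grp, length))
  rownames(smry) <- NULL
  list(replicates = reps, summary = smry)
}

#' Multiplicity of infection
#'
#' @param pfu infecting phage particles (plaque-forming units).
#' @param cfu host cells (colony-forming units), must be > 0.
#' @return MOI = pfu / cfu.
#' @export
moi <- function(pfu, cfu) {
  if (any(cfu <= 0)) stop("MOI undefined: cfu must be > 0")
  pfu / cfu
}

#' Efficiency of plaquing
#'
#' EOP is the ratio of phage pfus produced on a lawn of the test (mutant)
#' strain to pfus produced on the wild-type lawn. EOP 1 means full
#' susceptibility, EOP 0 complete resistance.
#'
#' @param mutant_pfu pfus on the test-strain lawn (>= 0).
#' @param wildtype_pfu pfus on the wild-type lawn (> 0).
#' @return numeric EOP values.
#' @export
eop <- function(mutant_pfu, wildtype_pfu) {
  if (any(wildtype_pfu <= 0))
    stop("EOP undefined: wild-type pfu must be > 0 (assay invalid)")
  if (any(mutant_pfu < 0)) stop("mutant pfu must be >= 0")
  mutant_pfu / wildtype_pfu
}

#' Tukey's multiple comparisons of group means
#'
#' Pairwise comparisons via the studentized-range distribution on the pooled
#' within-group variance (Tukey HSD, Tukey-Kramer for unequal group sizes):
#' `q = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with adjusted
#' p-value `P(Q_{k, N-k} >= q)`. Groups with fewer than 2 values are
#' excluded with a warning. Significance stars follow the usual convention
#' (* p < .05, ** p < .01, *** p < .001).
#'
#' @param values numeric response vector.
#' @param groups group labels parallel to `values` (>= 2 usable groups).
#' @return data.frame: group1, group2, diff (mean2 - mean1), q, p_adj,
#'   signif.
#' @export
tukey_compare <- function(values, groups) {
  groups <- as.character(groups)
  n_by <- table(groups)
  small <- names(n_by)[n_by < 2]
  if (length(small) > 0) {
    warning("excluding groups with < 2 values: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]
    groups <- groups[keep]
    n_by <- table(groups)
  }
  k <- length(n_by)
  if (k < 2) stop("need at least 2 groups with >= 2 values each")
  N <- length(values)
  means <- tapply(values, groups, mean)
  mse <- sum(tapply(values, groups,
                    function(x) sum((x - mean(x))^2))) / (N - k)
  dfree <- N - k
  prs <- utils::combn(sort(names(n_by)), 2)
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    stringsAsFactors = FALSE)
  out$diff <- as.numeric(means[out$group2] - means[out$group1])
  se <- as.numeric(sqrt(mse / 2 * (1 / n_by[out$group1] +
                                     1 / n_by[out$group2])))
  out$q <- abs(out$diff) / se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = dfree,
                             lower.tail = FALSE)
  out$p_adj[is.nan(out$q)] <- 1  # all values identical: no evidence
  out$signif <- cut(out$p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", ""))
  out$signif <- as.character(out$signif)
  rownames(out) <- NULL
  out
}

#' Quantile-quantile normality diagnostic
#'
#' Pairs the ordered sample with standard-normal quantiles at plotting
#' positions `(i - 0.5)/n` and reports their correlation; values close to 1
#' indicate compatibility with normality. This mirrors graphical QQ usage
#' and is a diagnostic, not a formal test.
#'
#' @param values numeric vector (n >= 3).
#' @return list with `points` (data.frame: theoretical, sample) and
#'   `correlation` (NA with a message element when the input is constant).
#' @export
qq_normality <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  pp <- (seq_len(n) - 0.5) / n
  pts <- data.frame(theoretical = stats::qnorm(pp), sample = sort(values))
  if (stats::sd(values) == 0)
    return(list(points = pts, correlation = NA_real_,
                message = "constant input: correlation undefined"))
  list(points = pts, correlation = stats::cor(pts$theoretical, pts$sample))
}
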