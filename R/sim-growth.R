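#' Default growth scenario for the community experiment
#'
#' True titers (per ml of harvested material) per condition and day that
#' encode the qualitative outcome of the community experiment: the host
#' grows to high density alone or with fungi; with phage it crashes on day
#' 1, recovers on day 2 (selection of resistant mutants) and declines on day
#' 3; with phage and fungi together it goes extinct by day 3 (titer 0).
#' Phage titers stay high except in the full community, where they drop on
#' day 3.
#'
#' @param conditions condition labels (defaults match [sim_config()]).
#' @return data.frame: condition, day, unit ("cfu"/"pfu"), titer (per ml).
#' @export
default_growth_scenario <- function(conditions = c("alone", "phage", "fungi",
                                                   "phage_fungi")) {
  cfu <- data.frame(
    condition = rep(conditions, each = 3),
    day = rep(1:3, times = 4),
    unit = "cfu",
    titer = c(5e8, 1e9, 2e9,      # alone
              5e6, 5e8, 2e7,      # phage: dip, recover, decline
              4e8, 8e8, 1.5e9,    # fungi
              5e6, 2e5, 0),       # phage + fungi: extinct by day 3
    stringsAsFactors = FALSE)
  pfu <- data.frame(
    condition = rep(c("phage", "phage_fungi"), each = 3),
    day = rep(1:3, times = 2),
    unit = "pfu",
    titer = c(1e9, 1e9, 1e9,
              1e9, 8e8, 2e8),
    stringsAsFactors = FALSE)
  rbind(cfu, pfu)
}

#' Simulate dilution-plating counts from true titers
#'
#' For each biological replicate and technical replicate, a plating dilution
#' is chosen to target roughly `target_count` colonies/plaques (clamped to
#' dilution <= 1) and the observed count is Poisson with mean
#' `titer * volume * dilution`. A titer of exactly 0 yields zero counts at
#' an undiluted plate.
#'
#' @param scenario data.frame of true titers as in
#'   [default_growth_scenario()].
#' @param n_bio,n_tech biological and technical replicates per observation.
#' @param volume_ml plated volume in ml.
#' @param target_count intended countable colonies per plate.
#' @param seed integer seed.
#' @return data.frame of PlateObservations: condition, day, unit, bio_rep,
#'   tech_rep, dilution, volume_ml, count.
#' @export
simulate_growth_assay <- function(scenario = default_growth_scenario(),
                                  n_bio = 3L, n_tech = 3L, volume_ml = 0.1,
                                  target_count = 100, seed = 1L) {
  if (any(scenario$titer < 0)) stop("negative titers are not allowed")
  set.seed(seed + 5L)
  rows <- lapply(seq_len(nrow(scenario)), function(i) {
    titer <- scenario$titer[i]
    dil <- if (titer > 0)
      10^-max(0, ceiling(log10(titer * volume_ml / target_count))) else 1
    grid <- expand.grid(bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech))
    data.frame(condition = scenario$condition[i], day = scenario$day[i],
               unit = scenario$unit[i], bio_rep = grid$bio_rep,
               tech_rep = grid$tech_rep, dilution = dil,
               volume_ml = volume_ml,
               count = stats::rpois(nrow(grid), titer * volume_ml * dil),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
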