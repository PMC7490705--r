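# Published study inputs for the four focal monocot taxa intercepted on
# refrigerated-container air-intake grilles at the Port of Savannah
# (shipping seasons 2015-2016 and 2016-2017). These tables are inputs to
# the simulator and worked examples; nothing in the package depends on
# them being re-derivable from raw collection records.

#' Life-history and influx parameters of the four focal taxa
#'
#' Estimated total seed influx per season (KNN-regression estimates),
#' empirical germination and transplant-survivorship rates from the
#' season-2 trials, and literature-derived fecundity (lowest reported
#' seeds per plant per year for each taxon).
#'
#' @return A tibble with one row per taxon: `taxon`, `influx_season1`,
#'   `influx_season2` (seeds), `germination` and `survival` (proportions),
#'   `fecundity` (seeds per established individual per year).
#' @export
#' @examples
#' focal_taxa()
focal_taxa <- function() {
  tibble::tibble(
    taxon = c(
      "Saccharum spontaneum", "Typha sp(p).",
      "Phragmites sp(p).", "Andropogon sp(p)."
    ),
    influx_season1 = c(24065, 68, 2941, 351),
    influx_season2 = c(17375, 360, 9898, 2440),
    germination = c(0.09, 0.18, 0.26, 0.37),
    survival = c(0.47, 0.91, 0.89, 0.62),
    fecundity = c(2000, 250000, 9500, 100)
  )
}

#' Pooled germination-trial tallies of the four focal taxa
#'
#' Season-2 trial counts: seeds plated, seedlings germinated in 14-day
#' chamber trials, and seedlings surviving to transplant into 4-inch pots.
#'
#' @return A tibble `(taxon, seeds_plated, germinated, survived_transplant)`.
#' @export
#' @examples
#' tabulate_rates(focal_trial_tallies())
focal_trial_tallies <- function() {
  tibble::tibble(
    taxon = c(
      "Saccharum spontaneum", "Typha sp(p).",
      "Phragmites sp(p).", "Andropogon sp(p)."
    ),
    seeds_plated = c(1690L, 923L, 697L, 170L),
    germinated = c(160L, 164L, 180L, 63L),
    survived_transplant = c(75L, 149L, 160L, 39L)
  )
}

#' Container arrivals and sampling effort per season
#'
#' Total refrigerated-container arrivals of the target commodity, the
#' number sampled, and the number of on-port sampling visits, for the two
#' study seasons. `coverage_pct` is recomputed from the counts.
#'
#' @return A tibble `(season, containers_arrived, containers_sampled,
#'   visits, coverage_pct)`.
#' @export
#' @examples
#' season_sampling_summary()
season_sampling_summary <- function() {
  x <- tibble::tibble(
    season = c("Season 1", "Season 2"),
    containers_arrived = c(1858L, 1925L),
    containers_sampled = c(331L, 297L),
    visits = c(15L, 14L)
  )
  x$coverage_pct <- percent_of(x$containers_sampled, x$containers_arrived)
  x
}
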