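# Parameter sweeps over escape rate, survival rate and carrying capacity,
# and stage-flow accounting for alluvial-style summaries.

# Accept either the wide per-taxon table (influx_season1/influx_season2
# columns, as from focal_taxa()) or an already-long table with season and
# influx columns.
taxa_long <- function(taxa) {
  if (all(c("influx_season1", "influx_season2") %in% names(taxa))) {
    taxa <- taxa |>
      tidyr::pivot_longer(
        dplyr::starts_with("influx_season"),
        names_to = "season", names_prefix = "influx_season",
        values_to = "influx"
      ) |>
      dplyr::mutate(season = paste("Season", .data$season))
  }
  required <- c("taxon", "season", "influx", "germination", "survival", "fecundity")
  missing <- setdiff(required, names(taxa))
  if (length(missing) > 0) {
    stop("taxa table is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  taxa
}

#' Sweep establishment simulations over escape and survival grids
#'
#' Runs one simulation per grid cell (taxon x season x escape rate x
#' survival rate x carrying capacity) and records invaded sites after 4 and
#' 10 years and whether and when the population fully established. Swept
#' survival rates stand in for field mortality exceeding that seen under
#' controlled conditions; each taxon's empirical survivorship is appended
#' to the grid as an upper bound, and cells whose survival exceeds the
#' empirical value are flagged `v_above_observed`.
#'
#' @param taxa Per-taxon parameter table: either wide (as [focal_taxa()])
#'   or long with columns `taxon, season, influx, germination, survival,
#'   fecundity`. The `survival` column is the empirical upper bound.
#' @param e_grid Escape rates to sweep (default 0.01%--10%).
#' @param v_grid Survival rates to sweep; the empirical rate is appended
#'   per taxon unless `include_empirical = FALSE`.
#' @param S_values Carrying capacities to sweep.
#' @param years Simulated years (at least 4).
#' @param mode,replicates,rng_seed Simulation mode; stochastic cells report
#'   the median over `replicates` runs on per-cell substreams.
#' @param include_empirical Append each taxon's empirical survivorship to
#'   `v_grid`.
#' @return A tibble with one row per grid cell.
#' @export
#' @examples
#' sw <- run_sweep(focal_taxa()[1, ], e_grid = c(0.005, 0.01), S_values = 1000)
#' sw[, c("taxon", "season", "escape", "survival_used", "invaded_after_4y")]
run_sweep <- function(taxa,
                      e_grid = c(0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1),
                      v_grid = c(0.05, 0.10, 0.25, 0.50),
                      S_values = c(1000, 100),
                      years = 10,
                      mode = c("deterministic", "stochastic"),
                      replicates = 100,
                      rng_seed = 1L,
                      include_empirical = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(e_grid) > 0, length(S_values) > 0, years >= 4)
  taxa <- taxa_long(taxa)

  rows <- vector("list", 0L)
  for (i in seq_len(nrow(taxa))) {
    tx <- taxa[i, ]
    vv <- sort(unique(c(v_grid, if (include_empirical) tx$survival)))
    grid <- expand.grid(e = e_grid, v = vv, S = S_values)
    cell <- lapply(seq_len(nrow(grid)), function(j) {
      e <- grid$e[j]
      v <- grid$v[j]
      S <- grid$S[j]
      life <- life_history(tx$taxon, tx$germination, v, tx$fecundity)
      if (mode == "deterministic") {
        sim <- simulate_establishment(tx$influx, e, life, sites = S, years = years)
        traj <- sim$trajectory$invaded_sites
        fy <- sim$fully_established_year
      } else {
        reps <- simulate_replicates(
          tx$influx, e, life,
          sites = S, years = years, replicates = replicates,
          rng_seed = derive_seed(rng_seed, c(tx$taxon, tx$season, e, v, S))
        )
        traj <- apply(reps, 1, median)
        fy <- if (any(traj >= S)) which(traj >= S)[1] else NA_integer_
      }
      tibble::tibble(
        taxon = tx$taxon, season = tx$season, influx = tx$influx,
        escape = e, survival_used = v,
        v_above_observed = v > tx$survival, sites = S,
        invaded_after_4y = traj[4],
        invaded_after_10y = traj[min(10, years)],
        fully_established = !is.na(fy),
        fully_established_year = fy
      )
    })
    rows <- c(rows, cell)
  }
  dplyr::bind_rows(rows)
}

#' Stage-flow table at a fixed escape rate
#'
#' Emits the influx -> escaped -> germinated -> survived -> reproduced seed
#' chain per taxon and season, the quantities behind alluvial-style plots.
#' Defaults to the deterministic expectation at a 1% escape rate.
#'
#' @inheritParams run_sweep
#' @param escape Container escape rate applied to year-1 influx.
#' @param sites,years Simulation dimensions.
#' @param mode,rng_seed As in [simulate_establishment()].
#' @return A tibble: one row per taxon, season and year with the stage
#'   quantities and the invaded-site count.
#' @export
#' @examples
#' flow <- stage_flow_report(focal_taxa(), escape = 0.01, years = 1)
#' flow[flow$taxon == "Saccharum spontaneum", ]
stage_flow_report <- function(taxa, escape = 0.01, sites = 1000, years = 10,
                              mode = c("deterministic", "stochastic"),
                              rng_seed = NULL) {
  mode <- match.arg(mode)
  taxa <- taxa_long(taxa)
  out <- lapply(seq_len(nrow(taxa)), function(i) {
    tx <- taxa[i, ]
    life <- life_history(tx$taxon, tx$germination, tx$survival, tx$fecundity)
    sim <- simulate_establishment(
      tx$influx, escape, life,
      sites = sites, years = years, mode = mode,
      rng_seed = if (mode == "stochastic") {
        derive_seed(rng_seed %||% 1L, c(tx$taxon, tx$season))
      } else {
        NULL
      }
    )
    dplyr::bind_cols(
      tibble::tibble(
        taxon = tx$taxon, season = tx$season,
        escape = escape, year = sim$stage_flow$year
      ),
      sim$stage_flow[, -1],
      tibble::tibble(invaded_sites = sim$trajectory$invaded_sites)
    )
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
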