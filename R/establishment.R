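# Process-based mean-field simulation of nonnative plant establishment in
# port greenspaces. Four processes act multiplicatively on seed numbers:
# escape from shipping containers, germination, seedling survival, and
# reproduction of established individuals. State is the number of "invaded
# sites" -- 1-m^2 areas holding at least one reproductive individual -- out
# of S equally susceptible sites. Container influx N acts in year 1 only,
# thinned by the escape rate; from year 2 on, seed input is reproduction by
# invaded sites (one reproducing unit per site, f seeds each), facing only
# germination and survival. Established sites never die.

#' Life-history parameters of a focal taxon
#'
#' @param taxon Taxon label.
#' @param germination Per-seed germination probability in `[0, 1]`.
#' @param survival Per-seedling survival probability in `[0, 1]`.
#' @param fecundity Seeds produced per established individual per year
#'   (at least 1).
#' @return A `life_history` list.
#' @export
#' @examples
#' life_history("Saccharum spontaneum", 0.09, 0.47, 2000)
life_history <- function(taxon, germination, survival, fecundity) {
  assert_proportion(germination, "germination")
  assert_proportion(survival, "survival")
  assert_positive(fecundity, "fecundity")
  if (fecundity < 1) stop("`fecundity` must be at least 1.", call. = FALSE)
  structure(
    list(
      taxon = as.character(taxon), germination = germination,
      survival = survival, fecundity = fecundity
    ),
    class = "life_history"
  )
}

# Expected newly invaded sites from `survivors` surviving seedlings landing
# uniformly on S sites of which `invaded` are already occupied.
# Without collision correction, every survivor founds a new site until the
# empty sites run out (the min() cap); with it, survivors collide on sites
# as S * p(site hit) with p = 1 - (1 - 1/S)^survivors, applied to the empty
# fraction. The two agree away from saturation.
new_sites_expected <- function(survivors, invaded, sites, collision_correction) {
  empty <- sites - invaded
  if (collision_correction) {
    empty * (1 - (1 - 1 / sites)^survivors)
  } else {
    min(empty, survivors)
  }
}

#' Simulate establishment of a nonnative population around a port
#'
#' Runs the four-process model for `years` annual steps. In deterministic
#' mode every transition is replaced by its expectation and fractional
#' counts are carried without rounding (with roughly one expected founder,
#' premature rounding would extinguish the population by fiat). In
#' stochastic mode seeds escape, land on uniformly random sites, germinate
#' and survive as individual Bernoulli events; a site holding at least one
#' survivor becomes, and remains, invaded.
#'
#' @param influx Total container-borne seed influx `N` for the single
#'   introduction season (applied in year 1 only).
#' @param escape Escape rate `e` in `[0, 1]`: proportion of container-borne
#'   seeds landing on suitable ground. Applies only to year-1 influx.
#' @param life A [life_history()].
#' @param sites Number of available 1-m^2 sites `S` (carrying capacity).
#' @param years Number of simulated years.
#' @param mode `"deterministic"` (expectation) or `"stochastic"`.
#' @param collision_correction Deterministic mode only: account for several
#'   survivors landing on the same site via
#'   `empty * (1 - (1 - 1/S)^survivors)` instead of the plain `min()` cap.
#' @param rng_seed Optional seed (stochastic mode).
#' @return An object of class `establishment_sim` with
#'   \describe{
#'     \item{trajectory}{tibble `(year, invaded_sites)`; non-decreasing,
#'       bounded by `sites`.}
#'     \item{stage_flow}{tibble per year: `seeds_influx`, `seeds_escaped`,
#'       `germinated`, `survived`, `seeds_reproduced`.}
#'     \item{fully_established_year}{first year with all sites invaded, or
#'       `NA` if never.}
#'   }
#' @export
#' @examples
#' ph <- life_history("Phragmites sp(p).", 0.26, 0.10, 9500)
#' sim <- simulate_establishment(9898, escape = 0.01, life = ph)
#' sim$trajectory
simulate_establishment <- function(influx, escape, life,
                                   sites = 1000, years = 10,
                                   mode = c("deterministic", "stochastic"),
                                   collision_correction = FALSE,
                                   rng_seed = NULL) {
  mode <- match.arg(mode)
  assert_positive(influx, "influx", strict = FALSE)
  assert_proportion(escape, "escape")
  stopifnot(inherits(life, "life_history"))
  assert_count(sites, "sites", strict = TRUE)
  assert_count(years, "years", strict = TRUE)

  g <- life$germination
  v <- life$survival
  f <- life$fecundity

  run <- function() {
    invaded <- 0
    traj <- numeric(years)
    flow <- vector("list", years)
    for (y in seq_len(years)) {
      if (y == 1) {
        seeds_in <- influx
        escaped <- if (mode == "deterministic") {
          influx * escape
        } else {
          rbinom(1, as.integer(influx), escape)
        }
      } else {
        # local reproduction: no container-escape filter after year 1
        seeds_in <- invaded * f
        escaped <- seeds_in
      }

      if (mode == "deterministic") {
        germinated <- escaped * g
        survived <- germinated * v
        invaded <- invaded +
          new_sites_expected(survived, invaded, sites, collision_correction)
        invaded <- min(invaded, sites)
      } else {
        # short-circuit: expected survivors so large that every site is hit
        if (escaped * g * v > 50 * sites && invaded < sites) {
          germinated <- escaped * g
          survived <- germinated * v
          invaded <- sites
        } else {
          escaped <- as.numeric(escaped)
          germinated <- rbinom(1, as.integer(escaped), g)
          survived <- rbinom(1, germinated, v)
          if (survived > 0 && invaded < sites) {
            # sites are exchangeable: label 1..invaded as occupied
            hit <- sample.int(sites, survived, replace = TRUE)
            invaded <- invaded + length(unique(hit[hit > invaded]))
          }
        }
      }

      traj[y] <- invaded
      flow[[y]] <- tibble::tibble(
        year = y,
        seeds_influx = seeds_in,
        seeds_escaped = escaped,
        germinated = germinated,
        survived = survived,
        seeds_reproduced = invaded * f
      )
    }
    full <- which(traj >= sites)
    structure(
      list(
        trajectory = tibble::tibble(year = seq_len(years), invaded_sites = traj),
        stage_flow = dplyr::bind_rows(flow),
        fully_established_year = if (length(full) > 0) full[1] else NA_integer_,
        config = list(
          influx = influx, escape = escape, life = life, sites = sites,
          years = years, mode = mode,
          collision_correction = collision_correction
        )
      ),
      class = "establishment_sim"
    )
  }

  if (mode == "stochastic") with_seed(rng_seed, run()) else run()
}

#' @export
print.establishment_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<establishment_sim> %s: N = %s, e = %g, g = %g, v = %g, f = %s, S = %d (%s)\n",
    cfg$life$taxon, format(cfg$influx, big.mark = ","), cfg$escape,
    cfg$life$germination, cfg$life$survival,
    format(cfg$life$fecundity, big.mark = ","), cfg$sites, cfg$mode
  ))
  cat(sprintf(
    "  invaded sites by year: %s\n",
    paste(signif(x$trajectory$invaded_sites, 3), collapse = " ")
  ))
  if (!is.na(x$fully_established_year)) {
    cat(sprintf("  fully established in year %d\n", x$fully_established_year))
  }
  invisible(x)
}

#' Replicate stochastic establishment runs
#'
#' Runs [simulate_establishment()] in stochastic mode `replicates` times on
#' independent substreams derived from one master seed.
#'
#' @inheritParams simulate_establishment
#' @param replicates Number of independent replicates.
#' @param rng_seed Master seed.
#' @return A `years x replicates` matrix of invaded-site counts.
#' @export
simulate_replicates <- function(influx, escape, life,
                                sites = 1000, years = 10,
                                replicates = 100, rng_seed = 1L) {
  assert_count(replicates, "replicates", strict = TRUE)
  vapply(seq_len(replicates), function(r) {
    simulate_establishment(
      influx, escape, life,
      sites = sites, years = years,
      mode = "stochastic",
      rng_seed = derive_seed(rng_seed, c("rep", r))
    )$trajectory$invaded_sites
  }, numeric(years))
}
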