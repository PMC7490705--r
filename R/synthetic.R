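# Synthetic season generator: arrival schedules, interception samples and
# germination/survival trials with known ground truth. The generator emulates
# the statistical structure the downstream estimators assume -- a roughly
# constant stream of container arrivals over a ~32-week shipping season,
# unimodal (or multimodal) seasonal seed-deposition intensity per taxon,
# overdispersed per-container counts, and biweekly sampling visits that
# record an explicit count (including zeros) for a random subset of the
# containers that arrived since the previous visit.

#' Describe one hitchhiking taxon for the season generator
#'
#' A taxon is characterised by a seasonal seed-deposition intensity (one or
#' more Gaussian bumps over the season), an expected season-wide seed total,
#' a per-container overdispersion parameter, and true germination and
#' survival probabilities used when generating trial outcomes.
#'
#' @param name Taxon label.
#' @param mean_total_seeds Expected total number of seeds deposited over all
#'   containers in the season.
#' @param peak_day Day-of-season (1-based) of the dispersal peak(s); may be a
#'   vector for multiple peaks.
#' @param peak_width_days Gaussian standard deviation(s) of the peak(s), in
#'   days; recycled against `peak_day`.
#' @param peak_weight Relative mass of each peak; recycled and normalised.
#' @param dispersion Overdispersion of per-container counts: the count for a
#'   container with mean `m` has variance `m + dispersion * m^2` (negative
#'   binomial; `dispersion = 0` gives Poisson counts).
#' @param germination_true,survival_true True per-seed germination and
#'   per-seedling survival probabilities.
#' @return A `taxon_spec` list.
#' @export
#' @examples
#' taxon_spec("Saccharum-like", mean_total_seeds = 10000)
taxon_spec <- function(name,
                       mean_total_seeds,
                       peak_day = 100,
                       peak_width_days = 20,
                       peak_weight = 1,
                       dispersion = 1,
                       germination_true = 0.1,
                       survival_true = 0.5) {
  assert_positive(mean_total_seeds, "mean_total_seeds", strict = FALSE)
  assert_positive(peak_width_days, "peak_width_days")
  assert_positive(dispersion, "dispersion", strict = FALSE)
  assert_proportion(germination_true, "germination_true")
  assert_proportion(survival_true, "survival_true")
  k <- max(length(peak_day), length(peak_width_days), length(peak_weight))
  structure(
    list(
      name = as.character(name),
      mean_total_seeds = mean_total_seeds,
      peak_day = rep_len(peak_day, k),
      peak_width_days = rep_len(peak_width_days, k),
      peak_weight = rep_len(peak_weight, k) / sum(rep_len(peak_weight, k)),
      dispersion = dispersion,
      germination_true = germination_true,
      survival_true = survival_true
    ),
    class = "taxon_spec"
  )
}

#' Describe a shipping season for the synthetic generator
#'
#' Defaults emulate the scale of an August--February refrigerated-container
#' season: 32 weeks of steady arrivals summing to ~1,900 containers, sampled
#' roughly once every two weeks at ~16% coverage.
#'
#' @param season_start First arrival date (`Date` or ISO string).
#' @param n_weeks Number of weeks in the season.
#' @param weekly_containers Container arrivals per week (length `n_weeks`, or
#'   a single value recycled).
#' @param taxa List of [taxon_spec()] objects.
#' @param sampling_interval_days Days between sampling visits.
#' @param sampled_fraction Probability that a container arriving between two
#'   visits is sampled at the later visit.
#' @param rng_seed Integer seed making the generated season reproducible.
#' @return A `season_spec` list.
#' @export
#' @examples
#' season_spec(taxa = list(taxon_spec("A", mean_total_seeds = 5000)))
season_spec <- function(season_start = as.Date("2015-08-13"),
                        n_weeks = 32,
                        weekly_containers = 59L,
                        taxa = list(),
                        sampling_interval_days = 14,
                        sampled_fraction = 0.16,
                        rng_seed = 1L) {
  assert_count(n_weeks, "n_weeks", strict = TRUE)
  weekly_containers <- rep_len(weekly_containers, n_weeks)
  assert_count(weekly_containers, "weekly_containers")
  assert_count(sampling_interval_days, "sampling_interval_days", strict = TRUE)
  assert_proportion(sampled_fraction, "sampled_fraction")
  if (!all(vapply(taxa, inherits, logical(1), "taxon_spec"))) {
    stop("`taxa` must be a list of taxon_spec objects.", call. = FALSE)
  }
  structure(
    list(
      season_start = as.Date(season_start),
      n_weeks = as.integer(n_weeks),
      weekly_containers = as.integer(weekly_containers),
      taxa = taxa,
      sampling_interval_days = as.integer(sampling_interval_days),
      sampled_fraction = sampled_fraction,
      rng_seed = as.integer(rng_seed)
    ),
    class = "season_spec"
  )
}

# Seasonal intensity curve (unnormalised) evaluated at 1-based day indices.
seasonal_weight <- function(taxon, day) {
  w <- numeric(length(day))
  for (j in seq_along(taxon$peak_day)) {
    w <- w + taxon$peak_weight[j] *
      exp(-((day - taxon$peak_day[j])^2) / (2 * taxon$peak_width_days[j]^2))
  }
  w
}

# Draw per-container counts with mean mu and variance mu + k * mu^2.
draw_counts <- function(n, mu, dispersion) {
  counts <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    counts[pos] <- if (dispersion > 0) {
      rnbinom(sum(pos), size = 1 / dispersion, mu = mu[pos])
    } else {
      rpois(sum(pos), mu[pos])
    }
  }
  counts
}

#' Generate a full synthetic shipping season
#'
#' Simulates every container arrival of the season, assigns each container a
#' seed count per taxon from an overdispersed count distribution whose mean
#' follows the taxon's seasonal intensity curve, then simulates biweekly
#' sampling visits. A visit samples each container that arrived since the
#' previous visit with probability `sampled_fraction` and records its counts
#' (explicit zeros included) under the visit date. Ground-truth totals are
#' exact sums over all containers, sampled or not.
#'
#' @param spec A [season_spec()].
#' @return A list of class `seedflux_season` with elements
#'   \describe{
#'     \item{arrivals}{tibble `(date, containers)`, one row per arrival day.}
#'     \item{samples}{tibble `(date, container_id, taxon, seed_count)`, one
#'       row per sampled container and taxon; `date` is the visit date.}
#'     \item{containers}{tibble of every container's true counts
#'       `(container_id, arrival_date, taxon, seed_count)`.}
#'     \item{truth}{tibble `(taxon, true_total_influx)`.}
#'     \item{visits}{tibble `(date, n_arrived, n_sampled)` per visit.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
#' @examples
#' s <- generate_season(season_spec(
#'   n_weeks = 8,
#'   taxa = list(taxon_spec("A", mean_total_seeds = 500, peak_day = 28))
#' ))
#' s$truth
generate_season <- function(spec) {
  stopifnot(inherits(spec, "season_spec"))
  with_seed(spec$rng_seed, {
    n_days <- spec$n_weeks * 7L
    dates <- spec$season_start + 0:(n_days - 1)

    # steady within-week arrivals: spread each week's containers over its
    # 7 days, remainder to the earliest days
    daily <- integer(n_days)
    for (w in seq_len(spec$n_weeks)) {
      cw <- spec$weekly_containers[w]
      base <- cw %/% 7L
      extra <- cw %% 7L
      idx <- (w - 1L) * 7L + 1:7
      daily[idx] <- base + c(rep(1L, extra), rep(0L, 7L - extra))
    }

    arrivals <- tibble::tibble(date = dates, containers = daily)
    total_containers <- sum(daily)
    container_day <- rep(seq_len(n_days), daily)
    container_id <- sprintf("C%05d", seq_len(total_containers))

    # true per-container counts for every taxon
    per_taxon <- lapply(spec$taxa, function(tx) {
      w <- seasonal_weight(tx, seq_len(n_days))
      denom <- sum(daily * w)
      mu_day <- if (denom > 0) tx$mean_total_seeds * w / denom else rep(0, n_days)
      draw_counts(total_containers, mu_day[container_day], tx$dispersion)
    })
    taxa_names <- vapply(spec$taxa, `[[`, character(1), "name")

    containers <- tibble::tibble(
      container_id = rep(container_id, times = length(spec$taxa)),
      arrival_date = rep(dates[container_day], times = length(spec$taxa)),
      taxon = rep(taxa_names, each = total_containers),
      seed_count = as.integer(unlist(per_taxon, use.names = FALSE))
    )

    truth <- tibble::tibble(
      taxon = taxa_names,
      true_total_influx = vapply(per_taxon, function(x) sum(as.numeric(x)), numeric(1))
    )

    # biweekly visits: each samples containers arrived since the last visit
    visit_day <- seq(spec$sampling_interval_days, n_days,
      by = spec$sampling_interval_days
    )
    # close out the season: a final visit covers any partial last window
    if (length(visit_day) == 0 || visit_day[length(visit_day)] < n_days) {
      visit_day <- c(visit_day, n_days)
    }
    prev <- c(0L, head(visit_day, -1L))
    sample_rows <- vector("list", length(visit_day))
    visit_info <- vector("list", length(visit_day))
    for (v in seq_along(visit_day)) {
      in_window <- which(container_day > prev[v] & container_day <= visit_day[v])
      take <- in_window[rbinom(length(in_window), 1L, spec$sampled_fraction) == 1L]
      visit_info[[v]] <- tibble::tibble(
        date = dates[visit_day[v]],
        n_arrived = length(in_window),
        n_sampled = length(take)
      )
      if (length(take) > 0 && length(spec$taxa) > 0) {
        sample_rows[[v]] <- tibble::tibble(
          date = dates[visit_day[v]],
          container_id = rep(container_id[take], times = length(spec$taxa)),
          taxon = rep(taxa_names, each = length(take)),
          seed_count = as.integer(unlist(
            lapply(per_taxon, `[`, take),
            use.names = FALSE
          ))
        )
      }
    }
    samples <- dplyr::bind_rows(sample_rows)
    if (nrow(samples) == 0) {
      samples <- tibble::tibble(
        date = as.Date(character()), container_id = character(),
        taxon = character(), seed_count = integer()
      )
    }

    structure(
      list(
        arrivals = arrivals,
        samples = samples,
        containers = containers,
        truth = truth,
        visits = dplyr::bind_rows(visit_info),
        spec = spec
      ),
      class = "seedflux_season"
    )
  })
}

#' @export
print.seedflux_season <- function(x, ...) {
  cat(sprintf(
    "<seedflux_season> %d containers over %d weeks, %d visits, %d sampled (%.0f%%)\n",
    sum(x$arrivals$containers), x$spec$n_weeks, nrow(x$visits),
    sum(x$visits$n_sampled),
    100 * sum(x$visits$n_sampled) / max(1, sum(x$arrivals$containers))
  ))
  print(x$truth)
  invisible(x)
}

#' Generate germination and transplant-survival trial outcomes
#'
#' Seeds are plated in dishes of 10 (the final dish may be partial); each
#' seed germinates independently with probability `g`, and each germinated
#' seedling survives to transplant with probability `v`.
#'
#' @param taxon Taxon label.
#' @param n_seeds Total number of seeds plated.
#' @param g True germination probability.
#' @param v True survival probability of a germinated seedling.
#' @param rng_seed Optional integer seed.
#' @return A tibble `(taxon, dish_id, seeds_plated, germinated,
#'   survived_transplant)`, one row per dish.
#' @export
#' @examples
#' generate_trials("A", n_seeds = 25, g = 1, v = 1)
generate_trials <- function(taxon, n_seeds, g, v, rng_seed = NULL) {
  assert_count(n_seeds, "n_seeds")
  assert_proportion(g, "g")
  assert_proportion(v, "v")
  with_seed(rng_seed, {
    if (n_seeds == 0) {
      return(tibble::tibble(
        taxon = character(), dish_id = integer(), seeds_plated = integer(),
        germinated = integer(), survived_transplant = integer()
      ))
    }
    n_dishes <- ceiling(n_seeds / 10)
    plated <- rep(10L, n_dishes)
    plated[n_dishes] <- n_seeds - 10L * (n_dishes - 1L)
    germinated <- rbinom(n_dishes, plated, g)
    survived <- rbinom(n_dishes, germinated, v)
    tibble::tibble(
      taxon = as.character(taxon),
      dish_id = seq_len(n_dishes),
      seeds_plated = plated,
      germinated = as.integer(germinated),
      survived_transplant = as.integer(survived)
    )
  })
}
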