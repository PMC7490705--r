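# Germination and post-transplant survivorship tabulation. Trials plate
# seeds in 10-seed dishes; taxon-level rates pool counts across dishes.
# Germination = germinated / plated; survivorship = survived to transplant
# into 4-inch pots / germinated. Printed percentages round half away from
# zero.

pool_tallies <- function(trials) {
  required <- c("taxon", "seeds_plated", "germinated", "survived_transplant")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop(
      "`trials` is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(
    trials$survived_transplant > trials$germinated |
      trials$germinated > trials$seeds_plated |
      trials$seeds_plated < 0 | trials$germinated < 0 |
      trials$survived_transplant < 0
  )
  if (length(bad) > 0) {
    stop(
      "Inconsistent tally (need survived <= germinated <= plated >= 0) at row(s): ",
      paste(head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  trials |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      seeds_plated = sum(.data$seeds_plated),
      germinated = sum(.data$germinated),
      survived_transplant = sum(.data$survived_transplant),
      .groups = "drop"
    )
}

#' Germination rate from a pooled trial tally
#'
#' @param tally One-row data frame (or pooled trial table for one taxon)
#'   with columns `taxon`, `seeds_plated`, `germinated`,
#'   `survived_transplant`.
#' @return The tally with `germination_raw` (proportion) and
#'   `germination_pct` (integer percent, half away from zero) appended.
#' @export
#' @examples
#' tabulate_germination(tibble::tibble(
#'   taxon = "Saccharum spontaneum",
#'   seeds_plated = 1690, germinated = 160, survived_transplant = 75
#' ))
tabulate_germination <- function(tally) {
  pooled <- pool_tallies(tally)
  if (any(pooled$seeds_plated == 0)) {
    stop("Germination rate undefined: no seeds plated.", call. = FALSE)
  }
  pooled$germination_raw <- pooled$germinated / pooled$seeds_plated
  pooled$germination_pct <- as.integer(round_half_up(100 * pooled$germination_raw))
  pooled
}

#' Post-transplant survivorship from a pooled trial tally
#'
#' The denominator is the number germinated, not the number plated. Taxa
#' with zero germination have an undefined survivorship and raise an error;
#' use [tabulate_rates()] to flag them instead.
#'
#' @inheritParams tabulate_germination
#' @return The tally with `survival_raw` and `survival_pct` appended.
#' @export
#' @examples
#' tabulate_survival(tibble::tibble(
#'   taxon = "Typha sp(p).",
#'   seeds_plated = 923, germinated = 164, survived_transplant = 149
#' ))
tabulate_survival <- function(tally) {
  pooled <- pool_tallies(tally)
  if (any(pooled$germinated == 0)) {
    stop("Survivorship undefined: no germination for taxon ",
      paste(pooled$taxon[pooled$germinated == 0], collapse = ", "),
      call. = FALSE
    )
  }
  pooled$survival_raw <- pooled$survived_transplant / pooled$germinated
  pooled$survival_pct <- as.integer(round_half_up(100 * pooled$survival_raw))
  pooled
}

#' Tabulate germination and survivorship for every taxon in a trial table
#'
#' Pools dish-level counts per taxon and computes both rates. Taxa that
#' never germinated get `NA` survivorship and `no_germination = TRUE`
#' rather than an error.
#'
#' @param trials Dish-level (or pooled) trial table with columns `taxon`,
#'   `seeds_plated`, `germinated`, `survived_transplant`.
#' @return A tibble with pooled counts, raw rates in `[0, 1]`, integer
#'   percentages and a `no_germination` flag.
#' @export
#' @examples
#' tabulate_rates(focal_trial_tallies())
tabulate_rates <- function(trials) {
  pooled <- pool_tallies(trials)
  if (any(pooled$seeds_plated == 0)) {
    stop("Germination rate undefined: no seeds plated for taxon ",
      paste(pooled$taxon[pooled$seeds_plated == 0], collapse = ", "),
      call. = FALSE
    )
  }
  pooled |>
    dplyr::mutate(
      germination_raw = .data$germinated / .data$seeds_plated,
      germination_pct = as.integer(round_half_up(100 * .data$germination_raw)),
      survival_raw = ifelse(.data$germinated > 0,
        .data$survived_transplant / .data$germinated, NA_real_
      ),
      survival_pct = ifelse(.data$germinated > 0,
        as.integer(round_half_up(100 * .data$survival_raw)), NA_integer_
      ),
      no_germination = .data$germinated == 0
    )
}

#' Per-dish germination percentages
#'
#' Dish-level rates (10-seed dishes) are retained for inspection; pooled
#' counts, not dish means, define the taxon-level rates.
#'
#' @param trials Dish-level trial table including a `dish_id` column.
#' @return The input with `dish_germination_pct` appended.
#' @export
dish_rates <- function(trials) {
  stopifnot(all(c("dish_id", "seeds_plated", "germinated") %in% names(trials)))
  trials |>
    dplyr::mutate(
      dish_germination_pct = ifelse(.data$seeds_plated > 0,
        round_half_up(100 * .data$germinated / .data$seeds_plated), NA_real_
      )
    )
}
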