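# Total seasonal seed influx by K-nearest-neighbours regression over
# sampling dates. Seeds-per-container is observed only on visit dates; the
# rate on every arrival date is predicted as the unweighted mean of the K
# nearest visit dates' observed rates (K = 2 by default), and the season
# total is N = sum_i s_hat_i * c_i over all arrival dates.

#' Aggregate per-container sample records into a per-date rate series
#'
#' For each sampling date, seeds-per-container is the total seed count of the
#' taxon across all containers sampled that date divided by the number of
#' containers sampled that date. Zero-seed containers count in the
#' denominator, so dates where the taxon was absent are retained as explicit
#' zero observations.
#'
#' @param samples Data frame with columns `date`, `container_id`, `taxon`,
#'   `seed_count` (one row per sampled container and taxon, as written by
#'   [generate_season()] or read by [read_samples()]).
#' @param taxon Taxon label to aggregate; `NULL` keeps all taxa.
#' @return A tibble `(taxon, date, seeds_per_container, n_containers)` sorted
#'   by taxon and date.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   date = as.Date("2015-10-01") + c(0, 0, 7, 7, 7),
#'   container_id = c("a", "b", "a", "c", "d"),
#'   taxon = "A",
#'   seed_count = c(2, 4, 0, 6, 0)
#' )
#' aggregate_samples(x)
aggregate_samples <- function(samples, taxon = NULL) {
  required <- c("date", "container_id", "taxon", "seed_count")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop(
      "`samples` is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(taxon)) {
    samples <- samples[samples$taxon %in% taxon, , drop = FALSE]
  }
  if (any(samples$seed_count < 0)) {
    stop("`seed_count` must be nonnegative.", call. = FALSE)
  }
  samples |>
    dplyr::group_by(.data$taxon, .data$date) |>
    dplyr::summarise(
      seeds_per_container = sum(.data$seed_count) / dplyr::n_distinct(.data$container_id),
      n_containers = dplyr::n_distinct(.data$container_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$taxon, .data$date)
}

#' Predict seeds-per-container on arbitrary dates by KNN regression
#'
#' Each query date is predicted as the unweighted mean of the observed rates
#' at the `k` training dates nearest in calendar days. Ties at equal distance
#' are broken in favour of the earlier date, and the neighbour list is
#' truncated to exactly `k` after sorting by (distance, date), so predictions
#' are deterministic. Query dates outside the sampled range use the `k`
#' nearest dates one-sided.
#'
#' @param series A rate series for one taxon: data frame with columns `date`
#'   and `seeds_per_container` (as from [aggregate_samples()]). Dates may be
#'   `Date` or numeric day numbers.
#' @param query_date Vector of dates (same type as `series$date`) to predict.
#' @param k Number of neighbours; must satisfy `1 <= k <= nrow(series)`.
#' @return Numeric vector of predicted seeds-per-container, one per query.
#' @export
#' @examples
#' series <- tibble::tibble(date = c(10, 20, 40), seeds_per_container = c(2, 4, 10))
#' knn_predict(series, query_date = c(15, 30, 40), k = 2)
knn_predict <- function(series, query_date, k = 2) {
  if (!all(c("date", "seeds_per_container") %in% names(series))) {
    stop("`series` needs columns `date` and `seeds_per_container`.", call. = FALSE)
  }
  if (length(unique(series$date)) != nrow(series)) {
    stop("`series` has duplicated sampling dates.", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    stop("`k` must be a positive integer.", call. = FALSE)
  }
  n <- nrow(series)
  if (n < k) {
    stop(sprintf("KNN needs at least k = %d training dates; have %d.", k, n),
      call. = FALSE
    )
  }
  train_day <- as.numeric(series$date)
  rate <- series$seeds_per_container
  vapply(as.numeric(query_date), function(q) {
    d <- abs(q - train_day)
    nb <- order(d, train_day)[seq_len(k)]
    mean(rate[nb])
  }, numeric(1))
}

#' Estimate total seasonal seed influx for one taxon
#'
#' Predicts seeds-per-container on every arrival date by [knn_predict()] and
#' accumulates `N = sum_i s_hat_i * c_i`, the predicted rate times the number
#' of containers arriving on date `i`, over the whole season.
#'
#' @param series Per-date rate series for one taxon (see [knn_predict()]).
#' @param arrivals Data frame with columns `date` and `containers`.
#' @param k Number of KNN neighbours (default 2).
#' @return An object of class `influx_estimate`: a list with `taxon`,
#'   `predictions` (tibble `date, s_hat, containers`), `N` (real-valued
#'   total) and `N_rounded` (nearest integer).
#' @export
#' @examples
#' series <- tibble::tibble(date = c(10, 30), seeds_per_container = c(1, 2))
#' arrivals <- tibble::tibble(date = c(10, 30), containers = c(100, 50))
#' estimate_total_influx(series, arrivals, k = 1)
estimate_total_influx <- function(series, arrivals, k = 2) {
  if (!all(c("date", "containers") %in% names(arrivals))) {
    stop("`arrivals` needs columns `date` and `containers`.", call. = FALSE)
  }
  if (anyDuplicated(arrivals$date)) {
    stop("`arrivals` has duplicated dates.", call. = FALSE)
  }
  assert_count(arrivals$containers, "containers")
  taxon <- if ("taxon" %in% names(series)) unique(as.character(series$taxon)) else NA_character_
  if (length(taxon) != 1) {
    stop("`series` must contain a single taxon; use aggregate_samples(taxon=).",
      call. = FALSE
    )
  }
  if (nrow(arrivals) == 0) {
    warning("Empty arrival schedule; total influx is 0.", call. = FALSE)
    predictions <- tibble::tibble(
      date = arrivals$date, s_hat = numeric(0), containers = numeric(0)
    )
    out <- list(taxon = taxon, predictions = predictions, N = 0, N_rounded = 0L)
    return(structure(out, class = "influx_estimate"))
  }
  s_hat <- knn_predict(series, arrivals$date, k = k)
  N <- sum(s_hat * arrivals$containers)
  structure(
    list(
      taxon = taxon,
      predictions = tibble::tibble(
        date = arrivals$date, s_hat = s_hat, containers = arrivals$containers
      ),
      N = N,
      N_rounded = as.integer(round_half_up(N))
    ),
    class = "influx_estimate"
  )
}

#' @export
print.influx_estimate <- function(x, ...) {
  cat(sprintf(
    "<influx_estimate> taxon %s: N = %.1f seeds (%d) over %d arrival dates\n",
    x$taxon, x$N, x$N_rounded, nrow(x$predictions)
  ))
  invisible(x)
}

#' Estimate influx for every taxon in a sample table
#'
#' Convenience wrapper: aggregates `samples` per taxon and runs
#' [estimate_total_influx()] against the common arrival schedule.
#'
#' @inheritParams aggregate_samples
#' @inheritParams estimate_total_influx
#' @param season_label Optional label copied into the result.
#' @return A tibble `(taxon, season, N, N_rounded)`.
#' @export
estimate_influx_all <- function(samples, arrivals, k = 2, season_label = NA_character_) {
  series_all <- aggregate_samples(samples)
  dplyr::bind_rows(lapply(split(series_all, series_all$taxon), function(s) {
    est <- estimate_total_influx(s, arrivals, k = k)
    tibble::tibble(
      taxon = est$taxon, season = season_label,
      N = est$N, N_rounded = est$N_rounded
    )
  }))
}
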