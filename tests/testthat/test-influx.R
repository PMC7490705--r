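# KNN influx estimation: aggregation arithmetic, neighbour selection and
# tie-breaking, the influx identity, and its invariants.

test_that("aggregation divides by all sampled containers, zeros included", {
  one_date <- tibble::tibble(
    date = as.Date("2015-10-01"),
    container_id = c("a", "b"), taxon = "T", seed_count = c(3, 1)
  )
  expect_equal(aggregate_samples(one_date)$seeds_per_container, 2.0)

  zeros <- tibble::tibble(
    date = as.Date("2015-10-01"),
    container_id = c("a", "b", "c"), taxon = "T", seed_count = c(0, 0, 0)
  )
  agg <- aggregate_samples(zeros)
  expect_equal(agg$seeds_per_container, 0)
  expect_equal(agg$n_containers, 3L)

  two_dates <- tibble::tibble(
    date = as.Date("2015-10-01") + c(0, 0, 7, 7, 7),
    container_id = c("a", "b", "a", "c", "d"),
    taxon = "T",
    seed_count = c(2, 4, 0, 6, 0)
  )
  agg2 <- aggregate_samples(two_dates)
  expect_equal(agg2$seeds_per_container, c(3.0, 2.0))
  expect_error(aggregate_samples(two_dates[, -1]), "missing column")
})

test_that("knn_predict averages the K nearest dates with earlier-date ties", {
  series <- tibble::tibble(
    date = c(10, 20, 40), seeds_per_container = c(2, 4, 10)
  )
  expect_equal(knn_predict(series, 15, k = 2), 3.0)
  expect_equal(knn_predict(series, 40, k = 1), 10.0)
  # day 30 is equidistant from days 20 and 40
  expect_equal(knn_predict(series, 30, k = 2), 7.0)
  expect_equal(knn_predict(series, 30, k = 1), 4.0)
  # extrapolation uses the nearest dates one-sided
  expect_equal(knn_predict(series, 0, k = 2), 3.0)
  expect_equal(knn_predict(series, 100, k = 2), 7.0)
  # k = n gives the global mean anywhere
  expect_equal(knn_predict(series, c(-5, 17, 300), k = 3), rep(16 / 3, 3))

  expect_error(knn_predict(series, 10, k = 4), "at least")
  expect_error(knn_predict(series, 10, k = 0), "positive integer")
  expect_error(
    knn_predict(tibble::tibble(date = c(1, 1), seeds_per_container = c(1, 2)), 1),
    "duplicated"
  )
})

test_that("knn tie-breaking works on Date objects as on day numbers", {
  series <- tibble::tibble(
    date = as.Date("2015-01-01") + c(9, 19, 39),
    seeds_per_container = c(2, 4, 10)
  )
  expect_equal(knn_predict(series, as.Date("2015-01-01") + 29, k = 1), 4.0)
})

test_that("total influx obeys N = sum(s_hat * c) and the constant-field identity", {
  series <- tibble::tibble(
    taxon = "T", date = c(10, 30), seeds_per_container = c(1, 2)
  )
  arrivals <- tibble::tibble(date = c(10, 30), containers = c(100, 50))
  est <- estimate_total_influx(series, arrivals, k = 1)
  expect_equal(est$N, 200)
  expect_equal(est$N, sum(est$predictions$s_hat * est$predictions$containers),
    tolerance = 1e-9
  )

  const <- tibble::tibble(
    taxon = "T", date = c(5, 15, 25), seeds_per_container = 3.5
  )
  many <- tibble::tibble(date = 1:30, containers = rep(7L, 30))
  expect_equal(estimate_total_influx(const, many, k = 2)$N, 3.5 * sum(many$containers))

  expect_warning(
    empty <- estimate_total_influx(series, arrivals[0, ], k = 1),
    "Empty"
  )
  expect_equal(empty$N, 0)
})

test_that("predictions are bounded by the observed series and scale linearly", {
  s <- generate_season(tiny_season(rng_seed = 21L))
  series <- aggregate_samples(s$samples)
  est <- estimate_total_influx(series, s$arrivals, k = 2)
  expect_true(all(est$predictions$s_hat >= min(series$seeds_per_container) - 1e-12))
  expect_true(all(est$predictions$s_hat <= max(series$seeds_per_container) + 1e-12))
  expect_equal(est$N, sum(est$predictions$s_hat * est$predictions$containers),
    tolerance = 1e-9
  )

  scaled <- dplyr::mutate(series, seeds_per_container = seeds_per_container * 3)
  expect_equal(estimate_total_influx(scaled, s$arrivals, k = 2)$N, est$N * 3,
    tolerance = 1e-9
  )
})

test_that("estimate_influx_all returns one rounded total per taxon", {
  spec <- season_spec(
    n_weeks = 6L, weekly_containers = 20L,
    taxa = list(
      taxon_spec("A", mean_total_seeds = 300, peak_day = 21),
      taxon_spec("B", mean_total_seeds = 0)
    ),
    rng_seed = 4L
  )
  s <- generate_season(spec)
  out <- estimate_influx_all(s$samples, s$arrivals, season_label = "S")
  expect_setequal(out$taxon, c("A", "B"))
  expect_equal(out$N_rounded[out$taxon == "B"], 0L)
  expect_equal(out$N_rounded, as.integer(round_half_up(out$N)))
})
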