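# Mean-field establishment simulator: hand-computed recurrences, stage-flow
# arithmetic, monotonicity and boundedness, and stochastic-mode agreement
# with closed-form oracles.

test_that("no influx or no escape means no invasion, ever", {
  life <- life_history("x", 0.5, 0.5, 100)
  expect_true(all(
    simulate_establishment(0, 0.1, life)$trajectory$invaded_sites == 0
  ))
  expect_true(all(
    simulate_establishment(5000, 0, life)$trajectory$invaded_sites == 0
  ))
  st <- simulate_establishment(5000, 0, life, mode = "stochastic", rng_seed = 1)
  expect_true(all(st$trajectory$invaded_sites == 0))
})

test_that("saturating parameters fill every site in year one", {
  life <- life_history("x", 1, 1, 1)
  sim <- simulate_establishment(2000, 1, life, sites = 1000)
  expect_equal(sim$trajectory$invaded_sites, rep(1000, 10))
  expect_equal(sim$fully_established_year, 1L)
})

test_that("the deterministic recurrence matches hand arithmetic (Phragmites-like)", {
  life <- life_history("Phragmites sp(p).", 0.26, 0.10, 9500)
  sim <- simulate_establishment(9898, 0.005 * 2, life, sites = 1000, years = 4)
  # year 1: 9898 * 0.01 * 0.26 * 0.10
  y1 <- 9898 * 0.01 * 0.26 * 0.10
  # year 2: survivors of y1 * 9500 seeds each, thinned by g * v
  y2 <- y1 + y1 * 9500 * 0.26 * 0.10
  expect_equal(sim$trajectory$invaded_sites[1], y1, tolerance = 1e-12)
  expect_equal(sim$trajectory$invaded_sites[2], y2, tolerance = 1e-12)
  expect_equal(sim$trajectory$invaded_sites[3], 1000) # capped
  expect_equal(sim$fully_established_year, 3L)
})

test_that("stage flow at 1% escape matches the multiplicative chain (Saccharum-like)", {
  life <- life_history("Saccharum spontaneum", 0.09, 0.47, 2000)
  sim <- simulate_establishment(17375, 0.01, life, sites = 1000, years = 2)
  f1 <- sim$stage_flow[1, ]
  expect_equal(f1$seeds_influx, 17375)
  expect_equal(f1$seeds_escaped, 173.75)
  expect_equal(f1$germinated, 173.75 * 0.09, tolerance = 1e-12)
  expect_equal(f1$survived, 173.75 * 0.09 * 0.47, tolerance = 1e-12)
  expect_equal(f1$seeds_reproduced, f1$survived * 2000, tolerance = 1e-9)
  # year 2 influx is reproduction only; no escape filter applies
  f2 <- sim$stage_flow[2, ]
  expect_equal(f2$seeds_influx, f1$seeds_reproduced)
  expect_equal(f2$seeds_escaped, f2$seeds_influx)
})

test_that("trajectories are non-decreasing, bounded by S, and flows are ordered", {
  for (seed in 1:10) {
    sim <- simulate_establishment(
      influx = 3000, escape = 0.02,
      life = life_history("x", 0.3, 0.4, 50),
      sites = 200, years = 8, mode = "stochastic", rng_seed = seed
    )
    traj <- sim$trajectory$invaded_sites
    expect_true(all(diff(traj) >= 0))
    expect_true(all(traj <= 200))
    fl <- sim$stage_flow
    expect_true(all(fl$survived <= fl$germinated + 1e-9))
    expect_true(all(fl$germinated <= fl$seeds_escaped + 1e-9))
    expect_true(all(fl$seeds_escaped <= fl$seeds_influx + 1e-9))
  }
})

test_that("invaded sites after four years grow with each parameter", {
  base <- list(N = 2000, e = 0.005, g = 0.2, v = 0.2, f = 30)
  run4 <- function(p) {
    simulate_establishment(
      p$N, p$e, life_history("x", p$g, p$v, p$f),
      sites = 1000, years = 4
    )$trajectory$invaded_sites[4]
  }
  y0 <- run4(base)
  for (par in names(base)) {
    up <- base
    up[[par]] <- base[[par]] * 1.5
    expect_gte(run4(up), y0)
  }
  # and strictly away from the cap
  expect_gt(run4(within(base, N <- 4000)), y0)
})

test_that("collision correction only matters near saturation", {
  life <- life_history("x", 0.3, 0.3, 40)
  plain <- simulate_establishment(1000, 0.01, life, sites = 1e6, years = 3)
  corr <- simulate_establishment(1000, 0.01, life,
    sites = 1e6, years = 3,
    collision_correction = TRUE
  )
  expect_equal(
    corr$trajectory$invaded_sites, plain$trajectory$invaded_sites,
    tolerance = 1e-3
  )
  # near saturation the corrected model invades strictly fewer sites
  tight <- simulate_establishment(300, 1, life_history("x", 1, 1, 2),
    sites = 100, years = 1, collision_correction = TRUE
  )
  expect_lt(tight$trajectory$invaded_sites[1], 100)
})

test_that("stochastic extinction fraction matches the binomial-thinning oracle", {
  # lambda = N * e * g * v = 0.5 expected founders; a replicate goes extinct
  # iff year 1 seeds no site, so P(extinct) = (1 - e*g*v)^N ~ exp(-lambda)
  N <- 500
  e <- 0.01
  g <- 0.5
  v <- 0.2
  life <- life_history("x", g, v, 50)
  reps <- simulate_replicates(N, e, life,
    sites = 1000, years = 10,
    replicates = 500, rng_seed = 99L
  )
  extinct <- mean(reps[10, ] == 0)
  p <- exp(-N * e * g * v)
  se <- sqrt(p * (1 - p) / 500)
  expect_lt(abs(extinct - p), 3 * se)
  # extinction at year 10 implies extinction from year 1 on
  expect_true(all(reps[, reps[10, ] == 0] == 0))
})

test_that("stochastic mean tracks the deterministic expectation away from saturation", {
  life <- life_history("x", 0.3, 0.5, 5)
  det <- simulate_establishment(2000, 0.01, life, sites = 1000, years = 3)
  reps <- simulate_replicates(2000, 0.01, life,
    sites = 1000, years = 3,
    replicates = 500, rng_seed = 7L
  )
  for (y in 1:3) {
    mc_se <- sd(reps[y, ]) / sqrt(ncol(reps))
    expect_lt(
      abs(mean(reps[y, ]) - det$trajectory$invaded_sites[y]),
      3 * mc_se + 0.05 # tiny allowance for site collisions
    )
  }
})

test_that("replicates are reproducible and independent of ordering", {
  life <- life_history("x", 0.3, 0.5, 5)
  a <- simulate_replicates(500, 0.02, life, years = 3, replicates = 20, rng_seed = 5L)
  b <- simulate_replicates(500, 0.02, life, years = 3, replicates = 20, rng_seed = 5L)
  expect_identical(a, b)
  expect_false(identical(a[, 1], a[, 2]))
})
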