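test_that("dose response is 1 at zero, peaks near the optimum, inhibits", {
  p <- simulation_params()
  expect_equal(dose_modifier(0, p), 1)
  expect_gt(dose_modifier(p$dose_optimum, p), 1)
  expect_lt(dose_modifier(p$dose_inhibition, p), 1)
  # near-peak: the maximum over a fine grid sits close to the optimum
  grid <- seq(0, 0.6, by = 1e-3)
  f <- dose_modifier(grid, p)
  expect_lt(abs(grid[which.max(f)] - p$dose_optimum), 0.01)
  expect_equal(max(f), p$dose_peak, tolerance = 0.01)
  expect_error(dose_modifier(-0.1, p), "molarity")
})

test_that("parameter constructor enforces scenario consistency", {
  expect_error(simulation_params(x0 = 2, k_capacity = 1.5), "x0")
  expect_error(simulation_params(ash_fraction = 1.2), "ash_fraction")
  expect_error(simulation_params(noise_cv = -0.1), "noise_cv")
  expect_error(simulation_params(dose_peak = 0.9), "dose_peak")
})

test_that("same parameters and seed give bitwise-identical simulations", {
  p <- simulation_params(noise_cv = 0.08, seed = 33)
  s1 <- simulate_culture(p)
  s2 <- simulate_culture(p)
  expect_identical(s1$truth, s2$truth)
  expect_identical(tidy(s1$observations), tidy(s2$observations))
  s3 <- simulate_culture(simulation_params(noise_cv = 0.08, seed = 34))
  expect_false(identical(tidy(s1$observations), tidy(s3$observations)))
})

test_that("without events or dosing, growth approaches capacity ungated", {
  p <- simulation_params(nahco3_molarity = 0, noise_cv = 0,
                         lsi_threshold = 1.5)
  sim <- simulate_culture(p, events = NULL, horizon_days = 30, dt = 0.05)
  final <- sim$truth[nrow(sim$truth), ]
  expect_gt(final$afdw, 0.99 * p$k_capacity)
  # sparged pH keeps the LSI below the gate, so nothing precipitates
  expect_true(all(sim$truth$lsi <= p$lsi_threshold))
  expect_true(all(sim$truth$precipitate == 0))
})

test_that("logistic update converges to the closed-form solution in dt", {
  p <- simulation_params(nahco3_molarity = 0, noise_cv = 0)
  closed_form <- function(t) {
    p$k_capacity / (1 + (p$k_capacity / p$x0 - 1) * exp(-p$mu * t))
  }
  err_at <- function(dt) {
    sim <- simulate_culture(p, events = NULL, horizon_days = 10, dt = dt)
    final <- sim$truth$afdw[nrow(sim$truth)]
    abs(final - closed_form(10))
  }
  e1 <- err_at(0.1)
  e2 <- err_at(0.01)
  expect_lt(e1, 0.01)              # O(dt) accuracy at the default step
  expect_lt(e2, e1 / 5)            # shrinks roughly linearly with dt
})

test_that("pH is pinned while sparging and rises monotonically after", {
  sim <- simulate_culture(simulation_params(), horizon_days = 14, dt = 0.1)
  tr <- sim$truth
  expect_true(all(tr$ph[tr$day <= 12] == sim$params$ph_sparged))
  post <- tr$ph[tr$day > 12]
  expect_true(all(diff(post) >= 0))
  expect_true(all(post <= sim$params$ph_air))
  expect_gt(max(post), 8.5)  # approaches the ambient-air asymptote
})

test_that("mass balance closes exactly across randomized parameter sets", {
  for (seed in 1:100) {
    p <- random_sim_params(seed)
    sim <- simulate_culture(p, horizon_days = 14, dt = 0.2)
    tr <- sim$truth
    n <- nrow(tr)
    ca_drawdown <- (tr$calcium[1] - tr$calcium[n]) / 1000
    alk_drawdown <- (tr$alkalinity[1] - tr$alkalinity[n]) / 1000
    expect_equal(tr$precipitate[n], ca_drawdown, tolerance = 1e-10)
    expect_equal(tr$precipitate[n], alk_drawdown, tolerance = 1e-10)
    # stepwise closure, not just in total
    expect_equal(diff(tr$precipitate), -diff(tr$calcium) / 1000,
                 tolerance = 1e-10)
    # the cap keeps chemistry strictly positive
    expect_true(all(tr$calcium > 0))
    expect_true(all(tr$alkalinity > 0))
    # cumulative precipitate never decreases
    expect_true(all(diff(tr$precipitate) > -1e-12))
  }
})

test_that("the calcium cap binds under aggressive precipitation", {
  p <- simulation_params(precip_rate_constant = 50, calcium = 300,
                         alkalinity = 2000, noise_cv = 0)
  sim <- simulate_culture(p, horizon_days = 14, dt = 0.1)
  tr <- sim$truth
  n <- nrow(tr)
  expect_lt(tr$calcium[n], 2)  # drained to the floor, never negative
  expect_gt(tr$calcium[n], 0)
  expect_equal(tr$precipitate[n], (tr$calcium[1] - tr$calcium[n]) / 1000)
})

test_that("doubling the rate constant cannot reduce cumulative precipitate", {
  base <- simulation_params(noise_cv = 0)
  fast <- simulation_params(noise_cv = 0,
                            precip_rate_constant = 2 * base$precip_rate_constant)
  final_precip <- function(p) {
    tr <- simulate_culture(p)$truth
    tr$precipitate[nrow(tr)]
  }
  expect_gt(final_precip(base), 0)
  expect_gte(final_precip(fast), final_precip(base))
})

test_that("a mid-run bicarbonate addition raises alkalinity stepwise", {
  ev <- tibble::tibble(day = c(8, 10), kind = c("co2_shutoff", "nahco3_addition"),
                       molarity = c(NA, 0.02))
  p <- simulation_params(nahco3_molarity = 0, noise_cv = 0,
                         lsi_threshold = 3)  # gate closed: isolate the step
  sim <- simulate_culture(p, events = ev, horizon_days = 14, dt = 0.1)
  tr <- sim$truth
  before <- tr$alkalinity[max(which(tr$day < 10))]
  after <- tr$alkalinity[min(which(tr$day > 10.05))]
  expect_equal(after - before, 0.02 * 50000)
  expect_error(
    simulate_culture(p, events = tibble::tibble(day = 20, kind = "co2_shutoff"),
                     horizon_days = 14),
    "horizon"
  )
})

test_that("simulator chemistry agrees with compute_lsi at every step", {
  sim <- simulate_culture(simulation_params(), horizon_days = 14, dt = 0.5)
  tr <- sim$truth
  check <- compute_lsi(tr[c("ph", "temperature_c", "tds", "calcium",
                            "alkalinity")])
  expect_equal(tr$lsi, check$lsi)
})

test_that("noiseless pipeline recovery is exact", {
  sim <- simulate_culture(simulation_params(noise_cv = 0, seed = 2))
  rec <- parameter_recovery_check(sim)
  expect_equal(nrow(rec), 4)
  expect_true(all(abs(rec$abs_error) < 1e-9))
})

test_that("noisy recovery has small bias in the extra-CO2 estimate", {
  rels <- vapply(1:20, function(s) {
    sim <- simulate_culture(simulation_params(noise_cv = 0.05, seed = s))
    rec <- parameter_recovery_check(sim)
    rec$rel_error[rec$quantity == "extra_co2_percent"]
  }, numeric(1))
  expect_lt(abs(mean(rels)), 0.05)
  expect_lt(stats::sd(rels), 0.15)
})
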