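test_that("consumption rate follows the Hill law in calcium", {
  pool <- aequorin_pool(1e6, lambda_max = 2, k_half = 5e-6, hill_n = 3)
  expect_identical(consumption_rate(0, pool), 0)
  expect_equal(consumption_rate(5e-6, pool), 1)           # half saturation
  expect_equal(consumption_rate(5e-5, pool), 2 * 1000 / 1001)  # 10x k_half
  expect_equal(consumption_rate(Inf, pool), 2)
  # monotone non-decreasing over a wide grid
  ca <- 10^seq(-9, -1, length.out = 200)
  expect_true(all(diff(consumption_rate(ca, pool)) >= 0))
  expect_error(consumption_rate(-1e-9, pool), "negative")
})

test_that("pool and scenario constructors validate their invariants", {
  expect_error(aequorin_pool(-1), "n_total")
  expect_error(aequorin_pool(1, lambda_max = 0), "lambda_max")
  expect_error(aequorin_pool(1, k_half = -1), "k_half")
  expect_error(aequorin_pool(1, hill_n = 0.5), "hill_n")
  expect_error(ca_scenario(list(seg_constant(1, 1e-7)), 10), "start at t = 0")
  expect_error(
    ca_scenario(list(seg_constant(0, 1e-7), seg_constant(0, 1e-6)), 10),
    "strictly increasing")
  expect_error(ca_scenario(list(seg_constant(0, 1e-7)), duration = 0), "duration")
  expect_error(seg_constant(0, -1), "non-negative")
})

test_that("constant-calcium discharge matches the exponential closed form", {
  pool <- aequorin_pool(3e5, lambda_max = 1)
  prof <- emit(pool, sat_scenario(duration = 12, dt = 0.01))
  lam <- consumption_rate(1e-2, pool)
  expect_equal(prof$rate, lam * pool$n_total * exp(-lam * prof$t),
               tolerance = 1e-6)
  # full discharge conserves the pool
  consumed <- prof$n_total - prof$n_remaining[length(prof$n_remaining)]
  expect_equal(consumed / pool$n_total, 1, tolerance = 1e-3)
})

test_that("emission scales linearly in pool size", {
  sc <- scenario_lysate(1e-5, inject_time = 5, duration = 20)
  p1 <- emit(aequorin_pool(1e6), sc)
  p2 <- emit(aequorin_pool(2e6), sc)
  expect_equal(p2$rate, 2 * p1$rate, tolerance = 1e-12)
  expect_equal(p2$n_remaining, 2 * p1$n_remaining, tolerance = 1e-12)
})

test_that("pool conservation and monotone discharge hold across scenarios", {
  pool <- aequorin_pool(5e6)
  scenarios <- list(
    sat_scenario(duration = 8, dt = 0.01),
    scenario_lysate(3e-6, inject_time = 5, duration = 30),
    ca_scenario(list(seg_constant(0, 1e-7),
                     seg_transient(5, 1e-7, 2e-6, tau_r = 2, tau_d = 10)),
                duration = 60),
    ca_scenario(list(seg_oscillation(0, 1e-7, 1e-6, period = 10)),
                duration = 60)
  )
  for (sc in scenarios) {
    prof <- emit(pool, sc)
    expect_true(all(prof$rate >= 0))
    expect_true(all(diff(prof$n_remaining) <= 0))
    expect_equal(prof$n_remaining[1], pool$n_total)
    consumed <- prof$n_total - prof$n_remaining[length(prof$n_remaining)]
    quad <- aequosim:::trapz(prof$t, prof$rate)
    expect_lt(abs(quad - consumed), 1e-3 * pool$n_total + 1e-9)
  }
})

test_that("too-coarse time steps are refused with a diagnostic", {
  pool <- aequorin_pool(1e6, lambda_max = 1)
  expect_error(emit(pool, sat_scenario(duration = 10, dt = 0.2)),
               "too coarse")
})

test_that("dilution series follows the geometric progression", {
  pool <- aequorin_pool(2e7)
  d <- dilution_series(pool, ratio = 2, n_points = 12)
  f <- attr(d, "factors")
  expect_equal(f, 2^-(0:11))
  expect_equal(log10(f[1] / f[12]), 11 * log10(2))
  expect_equal(log10(f[1] / f[12]), 3.31, tolerance = 0.002)
  expect_equal(vapply(d, `[[`, numeric(1), "n_total"), 2e7 * f)

  d2 <- dilution_series(pool, ratio = 2, n_points = 2)
  expect_equal(vapply(d2, `[[`, numeric(1), "n_total"), c(2e7, 1e7))
  d10 <- dilution_series(pool, ratio = 10, n_points = 3)
  expect_equal(attr(d10, "factors"), c(1, 0.1, 0.01))
  expect_error(dilution_series(pool, ratio = 1), "ratio")
  expect_error(dilution_series(pool, n_points = 1), "n_points")
})

test_that("live-cell scenario solves the ATP consumed fraction", {
  pool <- aequorin_pool(1e7)
  sc <- scenario_live_cell(pool, atp_fraction = 0.0375, atp_time = 10,
                           triton_time = 80, duration = 150)
  expect_equal(attr(sc, "atp_fraction_achieved"), 0.0375, tolerance = 2e-3)
  # Triton step discharges the remainder
  prof <- emit(pool, sc)
  expect_lt(prof$n_remaining[length(prof$n_remaining)] / pool$n_total, 0.01)
  # an unreachable fraction is refused explicitly
  expect_error(
    scenario_live_cell(pool, atp_fraction = 0.95, atp_time = 10,
                       triton_time = 12, duration = 30),
    "unreachable")
})

test_that("oscillation and mito scenarios hit their target peak rates", {
  pool <- aequorin_pool(1e7)
  sc <- scenario_oscillations(pool, peak_rate = 3e4, duration = 60)
  expect_equal(max(emit(pool, sc)$rate), 3e4, tolerance = 5e-3)
  expect_error(scenario_oscillations(pool, peak_rate = 6e4), "50 kHz")

  scm <- scenario_mito(pool, peak_rate = 2.2e6, duration = 60)
  expect_equal(max(emit(pool, scm)$rate), 2.2e6, tolerance = 5e-3)
  expect_error(scenario_mito(aequorin_pool(10), peak_rate = 2.2e6),
               "unreachable")
})
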