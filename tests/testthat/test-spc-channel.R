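test_that("arrival sampling reproduces Poisson means", {
  # constant 1 MHz signal, no dark: event-level mean within 3 sqrt(N)
  prof <- emission_constant(1e6, 1)
  s <- sample_arrivals(prof, detector_config(dcr = 0, seed = 11))
  expect_identical(s$mode, "event_list")
  expect_lt(abs(length(s$times) - 1e6), 3 * sqrt(1e6))
  expect_false(is.unsorted(s$times, strictly = TRUE))

  # dark only at the nominal dark-count rate
  dark <- sample_arrivals(emission_constant(0, 1),
                          detector_config(dcr = 904e3, seed = 12))
  expect_lt(abs(length(dark$times) - 904e3), 3 * sqrt(904e3))

  # silence
  s0 <- sample_arrivals(emission_constant(0, 1), detector_config(dcr = 0))
  expect_length(s0$times, 0)
})

test_that("the hybrid regime engages on rate or on expected event count", {
  cfg <- detector_config(dcr = 0, seed = 1)
  expect_identical(sample_arrivals(emission_constant(6e6, 0.5), cfg)$mode,
                   "binned")
  # sub-threshold rate but too many expected events
  expect_identical(
    sample_arrivals(emission_constant(0, 10),
                    detector_config(dcr = 904e3, seed = 1))$mode,
    "binned")
  b <- sample_arrivals(emission_constant(2e6, 1),
                       detector_config(dcr = 0, seed = 13,
                                       hybrid_max_events = 1))
  expect_identical(b$mode, "binned")
  expect_lt(abs(sum(b$counts) - 2e6), 3 * sqrt(2e6))
})

test_that("dead-time filtering matches its defining rules event by event", {
  # within one pulse duration the second event is lost
  two <- apply_deadtime(event_stream(c(1e-6, 1e-6 + 10e-9)),
                        detector_config())
  expect_equal(two$times, 1e-6)
  # a vanishing dead time keeps everything
  all_kept <- apply_deadtime(event_stream(c(1e-6, 1e-6 + 10e-9)),
                             detector_config(pulse_tau = 1e-12))
  expect_length(all_kept$times, 2)
  # paralyzable vs non-paralyzable differ on chained near-misses
  times <- c(0, 20e-9, 40e-9)
  par <- apply_deadtime(event_stream(times), detector_config())
  expect_equal(par$times, 0)  # 2nd blocks, and re-extends over the 3rd
  npar <- apply_deadtime(event_stream(times),
                         detector_config(deadtime_model = "nonparalyzable"))
  expect_equal(npar$times, c(0, 40e-9))  # 3rd is 40 ns after the last *counted*
  expect_error(apply_deadtime(event_stream(c(2e-6, 1e-6), span = c(0, 1)),
                              detector_config()),
               "unsorted")
})

test_that("event-level dead-time losses match the closed-form counted rate", {
  # 2 MHz homogeneous train, paralyzable: n exp(-n tau)
  prof <- emission_constant(2e6, 1)
  cfg <- detector_config(dcr = 0, seed = 21)
  counted <- length(apply_deadtime(sample_arrivals(prof, cfg), cfg)$times)
  expect_lt(abs(counted - 2e6 * exp(-0.06)), 3 * sqrt(counted))

  # non-paralyzable: n / (1 + n tau)
  cfg_np <- detector_config(dcr = 0, seed = 22,
                            deadtime_model = "nonparalyzable")
  counted_np <- length(apply_deadtime(sample_arrivals(prof, cfg_np), cfg_np)$times)
  expect_lt(abs(counted_np - 2e6 / 1.06), 3 * sqrt(counted_np))
})

test_that("counted-rate law has the expected shape and values", {
  cfg <- detector_config()
  expect_identical(expected_counted_rate(0, cfg), 0)
  expect_equal(expected_counted_rate(2e6, cfg), 2e6 * exp(-0.06))
  expect_equal(expected_counted_rate(2e6, cfg), 1883529, tolerance = 1e-6)
  cfg_np <- detector_config(deadtime_model = "nonparalyzable")
  expect_equal(expected_counted_rate(2e6, cfg_np), 2e6 / 1.06)
  # paralyzable counted rate peaks at n = 1/tau
  n_star <- 1 / cfg$pulse_tau
  expect_gt(expected_counted_rate(n_star, cfg),
            expected_counted_rate(n_star * 0.9, cfg))
  expect_gt(expected_counted_rate(n_star, cfg),
            expected_counted_rate(n_star * 1.1, cfg))
  # loss fraction is monotone in rate for both models
  rates <- seq(1e5, 2e7, length.out = 50)
  for (c2 in list(cfg, cfg_np)) {
    ratio <- expected_counted_rate(rates, c2) / rates
    expect_true(all(diff(ratio) < 0))
  }
})

test_that("pile-up probability is 1 - exp(-rate tau)", {
  cfg <- detector_config()
  expect_identical(pileup_probability(0, cfg), 0)
  expect_equal(pileup_probability(2e6, cfg), 1 - exp(-0.06))
  expect_equal(pileup_probability(2e6, cfg), 0.0582, tolerance = 1e-3)
  expect_equal(pileup_probability(3.5e6, cfg), 0.0997, tolerance = 1e-3)
})

test_that("windowed counting is exact and emulates the scaler depth", {
  s <- event_stream(seq(0.001, 0.091, by = 0.01), span = c(0, 0.1))
  tr <- count_windows(s, window = 0.1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$freq, 100)

  empty <- count_windows(event_stream(numeric(0), span = c(0, 1)), 0.1)
  expect_equal(empty$counts, rep(0, 10))

  # frequency * window returns the counts exactly
  prof <- emission_constant(5e5, 2)
  tr2 <- count_windows(sample_arrivals(prof, detector_config(dcr = 0, seed = 31)))
  expect_equal(tr2$freq * attr(tr2, "window"), tr2$counts, tolerance = 1e-12)

  # a 4-bit scaler clips at 15 and raises the saturation flag
  s20 <- event_stream(seq(0, 0.099, length.out = 20), span = c(0, 0.1))
  clipped <- count_windows(s20, window = 0.1, scaler_bits = 4)
  expect_equal(clipped$counts, 15)
  expect_true(clipped$saturated)
})

test_that("window statistics of a dark trace are Poisson", {
  det <- detector_config(seed = 41)
  trace <- spc_simulate(emission_constant(0, 10), det)
  expect_equal(nrow(trace), 100L)
  mu <- expected_counted_rate(det$dcr, det)   # counted dark level
  sigma <- sqrt(mu * 0.1) / 0.1
  expect_lt(abs(mean(trace$freq) - mu), 3 * sigma / sqrt(100))
  expect_lt(abs(sd(trace$freq) - sigma), 4 * sigma / sqrt(2 * 99))
})

test_that("event-level and binned simulation agree at the window level", {
  prof <- emission_constant(1e6, 3)
  ev <- spc_simulate(prof, detector_config(dcr = 0, seed = 51))
  bn <- spc_simulate(prof, detector_config(dcr = 0, seed = 52,
                                           hybrid_max_events = 1))
  m1 <- mean(ev$freq); m2 <- mean(bn$freq)
  se <- sqrt(var(ev$freq) / nrow(ev) + var(bn$freq) / nrow(bn))
  expect_lt(abs(m1 - m2), 3 * se)
})

test_that("arrival sampling is reproducible for a fixed seed", {
  prof <- emission_constant(2e5, 1)
  cfg <- detector_config(seed = 99)
  expect_identical(sample_arrivals(prof, cfg)$times,
                   sample_arrivals(prof, cfg)$times)
  expect_identical(spc_simulate(prof, cfg), spc_simulate(prof, cfg))
})
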