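test_that("baseline subtraction removes the quiet-window mean", {
  tr <- make_count_trace(rep(250, 400), baseline_subtracted = FALSE)
  out <- baseline_subtract(tr, c(0, 30))
  expect_equal(out$freq, rep(0, 400))
  expect_equal(attr(out, "baseline_value"), 250)
  expect_true(attr(out, "baseline_subtracted"))

  # a known offset is removed to within the SE of the window mean
  det <- detector_config(seed = 81)
  dark <- spc_simulate(emission_constant(0, 40), det)
  out2 <- baseline_subtract(dark, c(0, 30))
  se <- sd(dark$freq) / sqrt(300)
  expect_lt(abs(mean(out2$freq[out2$t >= 30])), 4 * se)

  expect_error(baseline_subtract(tr, c(100, 200)), "empty")
  expect_error(baseline_subtract(tr, c(0, 0.5)), "10 samples")
})

test_that("integrated intensity counts photoelectrons consistently", {
  z <- make_count_trace(rep(0, 100))
  expect_identical(integrated_intensity(z, c(0, 10)), 0)
  expect_error(integrated_intensity(z, c(50, 60)), "outside")
  raw <- make_count_trace(rep(1, 100), baseline_subtracted = FALSE)
  expect_error(integrated_intensity(raw, c(0, 1)), "baseline")

  # two pools differing 2x give integrals differing 2x (sub-pile-up)
  sc <- ca_scenario(list(seg_constant(0, 1e-7), seg_constant(2, 1e-2)),
                    duration = 13, dt = 0.01)
  det <- detector_config(dcr = 0, seed = 82)
  ints <- vapply(c(1e5, 2e5), function(n) {
    prof <- emit(aequorin_pool(n, lambda_max = 1), sc)
    tr <- baseline_subtract(spc_simulate(prof, det), c(0, 1.5))
    integrated_intensity(tr, c(2, 13))
  }, numeric(1))
  # trivial baseline here (dcr = 0); Poisson error dominates
  expect_lt(abs(ints[2] - 2 * ints[1]), 3 * sqrt(4 * ints[1] + ints[2]))
})

test_that("SPC and CI integrals agree for sub-pile-up signals", {
  # same emission profile through both branches, dark-free: after charge
  # conversion the two integrals estimate the same photon count
  pool <- aequorin_pool(2e6, lambda_max = 0.2)
  prof <- emit(pool, scenario_lysate(1e-2, inject_time = 5, duration = 40))
  det <- detector_config(dcr = 0, seed = 83)
  qdc <- qdc_config(seed = 84)
  spc <- baseline_subtract(spc_simulate(prof, det), c(0, 5))
  ci <- baseline_subtract(block_average(integrate_gates(prof, det, qdc), 560),
                          c(0, 5))
  i_spc <- integrated_intensity(spc, c(5, 40))
  i_ci <- integrated_intensity(ci, c(5, 40))
  expect_lt(abs(i_spc - i_ci) / i_ci, 0.05)
})

test_that("peak frequency finds the smoothed maximum", {
  tri <- make_count_trace(c(0:10, 9:0))
  p1 <- peak_frequency(tri, smooth_width = 1)
  expect_equal(p1$peak_hz, 10)
  expect_equal(p1$t_peak, 1.0)
  # default smoothing averages the apex with its neighbours
  expect_equal(peak_frequency(tri)$peak_hz, mean(c(9, 10, 9)))
  expect_equal(peak_frequency(make_count_trace(rep(0, 50)))$peak_hz, 0)
  expect_error(peak_frequency(make_count_trace(numeric(0))), "empty")
})

test_that("log-log fits recover exact power laws and honour exclusions", {
  x <- 2^-(0:7)
  y <- 3 * x^1.7
  fit <- suppressWarnings(fit_loglog(x, y))
  expect_equal(fit$slope, 1.7, tolerance = 1e-10)
  expect_equal(fit$intercept, log2(3), tolerance = 1e-10)
  expect_equal(fit$slope_se, 0, tolerance = 1e-6)
  expect_equal(fit$n_used, 8L)

  expect_equal(suppressWarnings(fit_loglog(x, y, "lowest-3"))$excluded, 6:8)
  expect_equal(suppressWarnings(fit_loglog(x, y, "highest-3"))$excluded, 1:3)
  y_bad <- y; y_bad[4] <- -1
  expect_error(fit_loglog(x, y_bad), "non-positive")
  expect_s3_class(suppressWarnings(fit_loglog(x, y_bad, exclude = 4)),
                  "linearity_fit")
  expect_error(fit_loglog(x, y, exclude = 1:6), "fewer than 3")
})

test_that("slope confidence intervals cover unity on linear-response data", {
  # Poisson-sampled linear response, 50 seeded replicates
  x <- 2^-(0:7)
  mu <- 2e5 * x
  withr::with_seed(90, {
    covered <- vapply(1:50, function(i) {
      fit <- fit_loglog(x, rpois(8, mu))
      abs(fit$slope - 1) <= qt(0.975, 6) * fit$slope_se
    }, logical(1))
  })
  expect_gte(mean(covered), 0.9)
})

test_that("sensitivity ratio converts intercept gaps", {
  expect_equal(round(sensitivity_ratio(17.90, 17.09), 2), 1.75)
  expect_equal(sensitivity_ratio(5, 5), 1)
  expect_equal(sensitivity_ratio(6, 5), 2)
})

test_that("analytic LoD follows three-sigma dark statistics", {
  expect_equal(lod_analytic(904e3, 0.1)$lod, 3 * sqrt(904e3 / 0.1))
  expect_equal(lod_analytic(904e3, 0.1)$lod, 9020, tolerance = 1e-4)
  expect_equal(lod_analytic(904e3, 5e-6)$lod, 1.2756e6, tolerance = 1e-4)
  expect_identical(lod_analytic(0, 0.1)$lod, 0)
  # scaling: proportional to sqrt(dcr) and to 1/sqrt(dt)
  for (k in c(2, 5, 10)) {
    expect_equal(lod_analytic(k * 1e5, 0.1)$lod,
                 sqrt(k) * lod_analytic(1e5, 0.1)$lod)
    expect_equal(lod_analytic(1e5, k * 0.1)$lod,
                 lod_analytic(1e5, 0.1)$lod / sqrt(k))
  }
})

test_that("empirical LoD matches the analytic law under pure Poisson noise", {
  det <- detector_config(seed = 85)
  dark_spc <- spc_simulate(emission_constant(0, 30), det)
  emp <- lod_empirical(dark_spc)
  expect_lt(abs(emp$lod - lod_analytic(det$dcr, 0.1)$lod),
            0.15 * lod_analytic(det$dcr, 0.1)$lod)

  qdc <- qdc_config(noise_sigma = 0, seed = 86)
  dark_ci <- integrate_gates(emission_constant(0, 18), det, qdc)
  emp_ci <- lod_empirical(dark_ci)
  expect_lt(abs(emp_ci$lod - lod_analytic(det$dcr, qdc$gate)$lod),
            0.15 * lod_analytic(det$dcr, qdc$gate)$lod)

  expect_error(lod_empirical(make_count_trace(rep(0, 50))), "100 dark samples")
})

test_that("block averaging buys the square-root LoD improvement", {
  det <- detector_config(seed = 87)
  qdc <- qdc_config(seed = 88)  # default white electronic noise
  dark <- integrate_gates(emission_constant(0, 5), det, qdc)
  lod1 <- lod_empirical(dark)$lod
  lodK <- lod_empirical(block_average(dark, 100))$lod
  expect_lt(abs(lod1 / lodK - sqrt(100)) / sqrt(100), 0.15)
})

test_that("discharge ratio validates windows and recovers trivial cases", {
  tr <- make_count_trace(c(rep(0, 100), rep(10, 100), rep(0, 100),
                           rep(100, 100)))
  dr <- discharge_ratio(tr, c(10, 20), c(30, 40))
  expect_equal(dr$ratio, 0.1)
  expect_error(discharge_ratio(tr, c(10, 25), c(20, 40)), "disjoint")
  zero_t <- make_count_trace(c(rep(1, 100), rep(0, 300)))
  expect_error(discharge_ratio(zero_t, c(0, 5), c(20, 30)), "positive")
})
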