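test_that("noise-free glucose follows the closed-form depletion curve", {
  ds <- simulate_batch(noiseless_preset(), zero_noise(), n_points = 20,
                       dt = 0.4)
  expect_equal(ds$glucose$value[1], 55)
  # C = glc0 + (pi_glc/mu) * X0 = 55 + 12.5 * 0.1 = 56.25
  expected <- 56.25 - 12.5 * 0.1 * exp(0.4 * ds$glucose$time_h)
  expect_equal(ds$glucose$value, expected, tolerance = 1e-12)
  expect_equal(ds$biomass$value, 0.1 * exp(0.4 * ds$biomass$time_h),
               tolerance = 1e-12)
})

test_that("lag phase holds biomass and glucose flat, then grows", {
  p <- noiseless_preset(lag_h = 2)
  ds <- simulate_batch(p, zero_noise(), n_points = 20, dt = 0.5)
  before <- ds$biomass$time_h <= 2
  expect_true(all(ds$biomass$value[before] == 0.1))
  expect_true(all(diff(ds$biomass$value) >= 0))
})

test_that("same seed gives identical datasets, different seeds differ", {
  a <- make_dataset(noise = noise_model(seed = 42))
  b <- make_dataset(noise = noise_model(seed = 42))
  c <- make_dataset(noise = noise_model(seed = 43))
  expect_identical(a, b)
  expect_false(identical(a$biomass$value, c$biomass$value))
})

test_that("generation fails when glucose depletes before the 4th point", {
  p <- strain_preset(x0 = 5, mu = 0.6, pi_glc = 20, glc0 = 10)
  expect_error(simulate_batch(p, zero_noise(), n_points = 10, dt = 2),
               "depleted before the 4th")
})

test_that("expected monotonicity: glucose non-increasing, biomass non-decreasing", {
  ds <- simulate_batch(strain_preset(), zero_noise(), n_points = 30, dt = 0.5)
  expect_true(all(diff(ds$glucose$value) <= 1e-12))
  expect_true(all(diff(ds$biomass$value) >= -1e-12))
})

test_that("off-gas CO2 trace peaks within one sampling interval of depletion", {
  for (seed in 1:5) {
    ds <- make_dataset(noise = noise_model(seed = seed))
    w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
    t_dep <- log((55.5 + 4.82 / 0.45 * 0.1) * 0.45 / (4.82 * 0.1)) / 0.45
    expect_lte(abs(w$t_end - t_dep), 0.4 + 1e-9)
  }
})

test_that("analytic carbon balance matches hand arithmetic", {
  # pi_co2 chosen so that all uptake carbon is recovered: theta = 1
  p <- strain_preset(x0 = 0.1, mu = 0.4, pi_glc = 5,
                     pi_co2 = 6 * 5 - 0.4 * 0.45 / 0.012011,
                     co2_retention = 0)
  expect_equal(analytic_theta(p), 1, tolerance = 1e-12)

  # retention is linear in pi_co2: measured theta loses rho * pi_co2/(6 pi_glc)
  p2 <- strain_preset(x0 = 0.1, mu = 0.4, pi_glc = 5, pi_co2 = p$pi_co2,
                      co2_retention = 0.2)
  expect_equal(analytic_theta(p2, measured_only = TRUE),
               analytic_theta(p2) - 0.2 * p2$pi_co2 / (6 * 5),
               tolerance = 1e-12)

  # wild-type-like rates: direct arithmetic gives 0.823
  wt <- strain_preset(mu = 0.45, pi_glc = 4.82, pi_co2 = 6.94,
                      co2_retention = 0)
  expect_equal(round(analytic_theta(wt), 3), 0.823)
})

test_that("generator and analyzer agree at full closure parameters", {
  p <- strain_preset(x0 = 0.1, mu = 0.4, pi_glc = 5,
                     pi_co2 = 6 * 5 - 0.4 * 0.45 / 0.012011,
                     glc0 = 55, co2_retention = 0)
  ds <- simulate_batch(p, zero_noise(), n_points = 40, dt = 0.4)
  w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
  f <- fit_rates(ds, w)
  gb <- offgas_balance(ds, f, w)
  cb <- instantaneous_theta(f$mu, f$pi_glc, gb$pi_co2_mean)
  expect_equal(cb$theta, analytic_theta(p), tolerance = 0.01)
})

test_that("recovered carbon balance strictly decreases with CO2 retention", {
  thetas <- vapply(c(0, 0.1, 0.2, 0.3), function(rho) {
    p <- strain_preset(co2_retention = rho)
    ds <- simulate_batch(p, zero_noise(seed = 1), n_points = 40, dt = 0.4)
    w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
    f <- fit_rates(ds, w)
    gb <- offgas_balance(ds, f, w)
    instantaneous_theta(f$mu, f$pi_glc, gb$pi_co2_mean)$theta
  }, numeric(1))
  expect_true(all(diff(thetas) < 0))
})
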