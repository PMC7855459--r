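test_that("published strain-panel rates reproduce the published carbon balance", {
  rates <- anaplerosis_rates()
  # the five strains whose printed inputs recompute exactly at 2 decimals
  exact <- c("ATCC 13032 (WT)" = 0.82, "dpyc" = 0.80, "dpyc dodx" = 0.81,
             "dppc dmalE" = 0.79, "dppc dpyc (evolved)" = 0.78)
  for (s in names(exact)) {
    r <- rates[rates$strain == s, ]
    cb <- instantaneous_theta(r$mu, r$pi_glc, r$pi_co2)
    expect_equal(round(cb$theta, 2), unname(exact[s]), tolerance = 1e-12,
                 label = s)
    expect_equal(round(cb$theta, 2), r$theta_published, tolerance = 1e-12)
  }
})

test_that("carbon balance arithmetic and degenerate cases", {
  wt <- instantaneous_theta(0.45, 4.82, 6.94)
  expect_equal(wt$theta, (0.45 * 0.45 / 0.012011 + 6.94) / (6 * 4.82),
               tolerance = 1e-12)
  expect_equal(round(wt$theta, 3), 0.823)

  evolved <- instantaneous_theta(0.27, 3.74, 7.40)
  expect_equal(round(evolved$theta, 2), 0.78)

  none <- instantaneous_theta(0, 5, 0)
  expect_equal(none$theta, 0)
  expect_error(instantaneous_theta(0.4, 0, 5), "positive")
})

test_that("theta is scale-invariant and monotone in each rate", {
  base <- instantaneous_theta(0.45, 4.82, 6.94)$theta
  for (k in c(0.5, 2, 7)) {
    scaled <- instantaneous_theta(0.45 * k, 4.82 * k, 6.94 * k)$theta
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  expect_gt(instantaneous_theta(0.46, 4.82, 6.94)$theta, base)
  expect_gt(instantaneous_theta(0.45, 4.82, 7.2)$theta, base)
  expect_lt(instantaneous_theta(0.45, 5.0, 6.94)$theta, base)
})

test_that("error propagation matches the analytic partial derivatives", {
  # all inputs exact -> zero error, but the omega_c prior still contributes
  cp0 <- carbon_params(sd_omega_c = 0)
  expect_equal(propagate_theta_error(0.45, 4.82, 6.94, 0, 0, 0, cp0), 0)

  # single-term oracle: only omega_c uncertain
  sd_omega_only <- propagate_theta_error(0.45, 4.82, 6.94, 0, 0, 0)
  expect_equal(sd_omega_only, 0.45 / (0.012011 * 6 * 4.82) * 0.05,
               tolerance = 1e-12)
  expect_equal(sd_omega_only, 0.0648, tolerance = 1e-3)

  # quadrature sum with the full published wild-type sds; this is the
  # independent-propagation figure, deliberately not the published 0.089
  full <- propagate_theta_error(0.45, 4.82, 6.94, 0.04, 0.25, 0.71)
  theta <- instantaneous_theta(0.45, 4.82, 6.94)$theta
  by_hand <- sqrt((0.45 / 0.012011 / (6 * 4.82) * 0.04)^2 +
                    (0.71 / (6 * 4.82))^2 +
                    (theta / 4.82 * 0.25)^2 +
                    (0.45 / (0.012011 * 6 * 4.82) * 0.05)^2)
  expect_equal(full, by_hand, tolerance = 1e-12)
  expect_equal(full, 0.0965, tolerance = 1e-3)
})

test_that("sink decomposition partitions the uptake carbon", {
  wt <- instantaneous_theta(0.45, 4.82, 6.94)
  s <- sink_decomposition(wt)
  expect_equal(s[["biomass_fraction"]] + s[["co2_fraction"]], wt$theta,
               tolerance = 1e-12)
  expect_equal(sum(s), 1, tolerance = 1e-12)

  closure <- instantaneous_theta(0.4, 5, 6 * 5 - 0.4 * 0.45 / 0.012011)
  expect_equal(sink_decomposition(closure)[["gap_fraction"]], 0,
               tolerance = 1e-12)
})

test_that("retention produces a gap equal to the retained CO2 share", {
  p <- strain_preset(co2_retention = 0.2)
  full <- analytic_theta(p)
  meas <- analytic_theta(p, measured_only = TRUE)
  co2_share <- p$pi_co2 / (6 * p$pi_glc)
  expect_equal(full - meas, 0.2 * co2_share, tolerance = 1e-12)
})

test_that("carbon_balance objects tidy into a three-sink table", {
  cb <- carbon_balance(0.45, 4.82, 6.94, 0.04, 0.25, 0.71)
  td <- tidy(cb)
  expect_identical(td$sink, c("biomass", "co2", "gap"))
  expect_equal(sum(td$fraction_of_uptake), 1, tolerance = 1e-12)
  expect_false(is.na(glance(cb)$sd_theta))
})
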