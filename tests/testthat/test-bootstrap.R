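test_that("LHS places exactly one draw per marginal stratum", {
  m <- lhs_normal_perturb(means = c(2, -5, 0), sds = c(1, 3, 0.2), n = 10,
                          seed = 7)
  expect_equal(dim(m), c(10, 3))
  for (j in 1:3) {
    u <- pnorm(m[, j], mean = c(2, -5, 0)[j], sd = c(1, 3, 0.2)[j])
    expect_setequal(floor(u * 10), 0:9)
  }
})

test_that("LHS is deterministic given the seed and collapses as sd -> 0", {
  a <- lhs_normal_perturb(c(1, 2), c(0.1, 0.2), 8, seed = 3)
  b <- lhs_normal_perturb(c(1, 2), c(0.1, 0.2), 8, seed = 3)
  expect_identical(a, b)
  c <- lhs_normal_perturb(c(1, 2), c(0.1, 0.2), 8, seed = 4)
  expect_false(identical(a, c))

  tiny <- lhs_normal_perturb(c(1, 2), c(1e-12, 1e-12), 8, seed = 3)
  expect_equal(tiny[, 1], rep(1, 8), tolerance = 1e-9)
  expect_equal(tiny[, 2], rep(2, 8), tolerance = 1e-9)
})

test_that("stratified draws respect the n = 4 stratum bounds around N(0,1)", {
  # stratum midpoints of N(0,1) at n = 4: qnorm(c(.125,.375,.625,.875))
  m <- lhs_normal_perturb(0, 1, n = 4, seed = 11)
  z <- sort(m[, 1])
  bounds <- qnorm(seq(0, 1, by = 0.25))
  for (i in 1:4) {
    expect_gte(z[i], bounds[i])
    expect_lte(z[i], bounds[i + 1])
  }
  expect_equal(qnorm(c(0.125, 0.375, 0.625, 0.875)),
               c(-1.1503494, -0.3186394, 0.3186394, 1.1503494),
               tolerance = 1e-6)
})

test_that("bootstrap bounds are the sample percentiles (IQR at alpha = 0.25)", {
  ds <- make_dataset(noise = noise_model(seed = 11), n_points = 30, dt = 0.5)
  w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
  bt <- bootstrap_fit(ds, w, n = 100, alpha = 0.25, seed = 5)
  for (term in c("x0", "mu", "pi_glc", "c_const")) {
    x <- sort(bt$samples[[term]])
    # linear interpolation between closest ranks: h = (n-1)p + 1
    pct <- function(p) {
      h <- (length(x) - 1) * p + 1
      lo <- floor(h)
      x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
    }
    expect_equal(unname(bt$lower[term]), pct(0.25), tolerance = 1e-12)
    expect_equal(unname(bt$upper[term]), pct(0.75), tolerance = 1e-12)
  }
  expect_true(all(bt$lower <= bt$upper))
  expect_equal(bt$n_failed + nrow(bt$samples), bt$n_samples)
})

test_that("intervals collapse onto the point estimate as sds shrink", {
  ds <- make_dataset(noise = noise_model(seed = 13), n_points = 30, dt = 0.5)
  w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
  f <- fit_rates(ds, w)
  ds$biomass$sd <- ds$biomass$sd * 1e-6
  ds$glucose$sd <- ds$glucose$sd * 1e-6
  bt <- bootstrap_fit(ds, w, n = 50, seed = 2, fit = f)
  est <- c(x0 = f$x0, mu = f$mu, pi_glc = f$pi_glc, c_const = f$c_const)
  for (term in names(est)) {
    expect_equal(unname(bt$lower[term]), unname(est[term]),
                 tolerance = 1e-4)
    expect_equal(unname(bt$upper[term]), unname(est[term]),
                 tolerance = 1e-4)
  }
})

test_that("interval width grows with the measurement-noise scale", {
  ds0 <- make_dataset(noise = noise_model(seed = 17), n_points = 30, dt = 0.5)
  w <- detect_window(ds0$offgas_co2, ds0$biomass, glucose = ds0$glucose)
  width_at <- function(k) {
    ds <- ds0
    ds$biomass$sd <- k * ds$biomass$sd
    ds$glucose$sd <- k * ds$glucose$sd
    bt <- bootstrap_fit(ds, w, n = 150, seed = 23)
    unname(bt$upper["mu"] - bt$lower["mu"])
  }
  widths <- vapply(c(0.5, 1, 2), width_at, numeric(1))
  # allow slack for Monte-Carlo noise on top of monotone growth
  expect_lt(widths[1], widths[2] * 1.1)
  expect_lt(widths[2], widths[3] * 1.1)
  expect_lt(widths[1], widths[3])
})

test_that("the point estimate lies inside its own interquartile interval", {
  ds <- make_dataset(noise = noise_model(seed = 29))
  w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
  f <- fit_rates(ds, w)
  bt <- bootstrap_fit(ds, w, n = 200, alpha = 0.25, seed = 31, fit = f)
  expect_gte(f$mu, bt$lower[["mu"]] - 1e-9)
  expect_lte(f$mu, bt$upper[["mu"]] + 1e-9)
})

test_that("bootstrap is reproducible given the seed", {
  ds <- make_dataset(noise = noise_model(seed = 37), n_points = 30, dt = 0.5)
  w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
  a <- bootstrap_fit(ds, w, n = 60, seed = 19)
  b <- bootstrap_fit(ds, w, n = 60, seed = 19)
  expect_identical(a$samples, b$samples)
})
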