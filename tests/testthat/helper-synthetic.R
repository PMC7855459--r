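# Shared fixtures, built in code.

# canonical noiseless preset used in closed-form checks:
# X0 = 0.1 g/L, mu = 0.4/h, pi_glc = 5 -> C = 55 + 1.25 = 56.25 mmol/L
noiseless_preset <- function(...) {
  strain_preset(x0 = 0.1, mu = 0.4, pi_glc = 5, pi_co2 = 15.014,
                glc0 = 55, co2_retention = 0, ...)
}

zero_noise <- function(seed = 1) noise_model(0, 0, 0, seed = seed)

make_dataset <- function(preset = strain_preset(), noise = noise_model(),
                         n_points = 40, dt = 0.4, ...) {
  simulate_batch(preset, noise, n_points = n_points, dt = dt, ...)
}

# hand-built series for constructed-violation tests
series_tbl <- function(times, values, sds) {
  tibble::tibble(time_h = times, value = values, sd = sds)
}

# dataset assembled by hand (bypassing constructors) so invariant violations
# can be injected
raw_dataset <- function() {
  t <- 0:9
  b <- series_tbl(t, 0.1 * exp(0.4 * t), rep(0.01, 10))
  g <- series_tbl(t, pmax(56.25 - 1.25 * exp(0.4 * t), 0.1), rep(0.5, 10))
  o2 <- series_tbl(t, rep(20.5, 10), rep(0.02, 10))
  co2 <- series_tbl(t, c(seq(0.1, 1, length.out = 8), 0.8, 0.5),
                    rep(0.02, 10))
  list(biomass = structure(b, quantity = "biomass_cdw"),
       glucose = structure(g, quantity = "glucose"),
       offgas_o2 = structure(o2, quantity = "o2_out"),
       offgas_co2 = structure(co2, quantity = "co2_out"),
       gas = gas_conditions(), reactor_volume = 1, strain = "raw")
}
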