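# Synthetic batch-culture generator. Forward-simulates exponential growth,
# glucose depletion and the off-gas CO2/O2 traces implied by the gas balance,
# then overlays independent Gaussian measurement noise.

#' Strain preset for the synthetic generator
#'
#' True physiology of a simulated strain. Defaults mimic a glucose-grown
#' *C. glutamicum* wild type in a batch reactor: mu ~ 0.45/h, glucose uptake
#' ~ 4.8 mmol/gCDW/h, CO2 formation ~ 6.9 mmol/gCDW/h on 1 % (w/v) glucose.
#'
#' @param x0 Initial biomass, g/L.
#' @param mu Specific growth rate, 1/h.
#' @param pi_glc Specific glucose uptake rate, mmol/gCDW/h.
#' @param pi_co2 Specific CO2 formation rate, mmol/gCDW/h.
#' @param glc0 Initial glucose, mmol/L (55.5 is 1 % w/v).
#' @param co2_retention Fraction rho of produced CO2 retained in the broth as
#'   dissolved CO2/bicarbonate and therefore invisible to the off-gas
#'   analyzer; 0 <= rho < 1.
#' @param lag_h Lag time before exponential growth starts, h.
#'
#' @return A list of class `strain_preset`.
#' @export
strain_preset <- function(x0 = 0.1, mu = 0.45, pi_glc = 4.82, pi_co2 = 6.94,
                          glc0 = 55.5, co2_retention = 0.2, lag_h = 0) {
  stopifnot(x0 > 0, mu > 0, pi_glc > 0, pi_co2 > 0, glc0 > 0,
            co2_retention >= 0, co2_retention < 1, lag_h >= 0)
  structure(
    list(x0 = x0, mu = mu, pi_glc = pi_glc, pi_co2 = pi_co2, glc0 = glc0,
         co2_retention = co2_retention, lag_h = lag_h),
    class = "strain_preset"
  )
}

#' Measurement noise model for the synthetic generator
#'
#' Independent Gaussian noise per data point. Biomass noise defaults to 5 %
#' relative (the assumed relative error of CDW derived from biovolume),
#' glucose to 3 % relative, and off-gas fractions to an absolute analyzer
#' noise of 0.02 vol%.
#'
#' @param rel_sd_biomass Relative sd of biomass readings.
#' @param rel_sd_glucose Relative sd of glucose readings.
#' @param abs_sd_gas Absolute sd of gas volume fractions, vol%.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(rel_sd_biomass = 0.05, rel_sd_glucose = 0.03,
                        abs_sd_gas = 0.02, seed = 1L) {
  stopifnot(rel_sd_biomass >= 0, rel_sd_glucose >= 0, abs_sd_gas >= 0)
  structure(
    list(rel_sd_biomass = rel_sd_biomass, rel_sd_glucose = rel_sd_glucose,
         abs_sd_gas = abs_sd_gas, seed = as.integer(seed)),
    class = "noise_model"
  )
}

# True (noise-free) state trajectories of the forward model.
preset_trajectory <- function(preset, times) {
  tt <- pmax(times - preset$lag_h, 0)
  x <- preset$x0 * exp(preset$mu * tt)
  cglc_const <- preset$glc0 + (preset$pi_glc / preset$mu) * preset$x0
  glc <- cglc_const - (preset$pi_glc / preset$mu) * preset$x0 * exp(preset$mu * tt)
  list(biomass = x, glucose = glc, c_const = cglc_const)
}

# Time at which model glucose hits zero.
depletion_time <- function(preset) {
  cglc_const <- preset$glc0 + (preset$pi_glc / preset$mu) * preset$x0
  preset$lag_h +
    log(cglc_const * preset$mu / (preset$pi_glc * preset$x0)) / preset$mu
}

#' Simulate a batch cultivation dataset
#'
#' Forward-simulates exponential growth after an optional lag, the matching
#' glucose depletion curve, and the off-gas O2/CO2 traces obtained by pushing
#' the gas-phase CO2 release `(1 - rho) * pi_co2 * X(t) * V` through the
#' reactor gas balance (respiratory quotient 1 for the O2 trace). Biomass and
#' glucose are sampled until glucose depletion; off-gas is recorded on the
#' full grid, with the CO2 release decaying exponentially after depletion
#' (a stand-in for stripping of the dissolved CO2 pool, and what puts the
#' peak of the CO2 trace at the end of the exponential phase). Gaussian noise
#' per `noise_model` is added last; the recorded per-point sds equal the noise
#' magnitudes used (floored at a tiny positive value so that noise-free
#' datasets remain valid weighted-fit inputs, and at 0.05 mmol/L for glucose
#' near depletion).
#'
#' @param preset A [strain_preset()].
#' @param noise A [noise_model()].
#' @param n_points Number of sampling times (>= 4).
#' @param dt Sampling interval, h.
#' @param gas [gas_conditions()] of the run.
#' @param reactor_volume Working volume, L.
#' @param strain Strain label stored in the dataset.
#'
#' @return A [batch_dataset()].
#' @export
#' @examples
#' ds <- simulate_batch(strain_preset(), noise_model(seed = 7),
#'                      n_points = 40, dt = 0.5)
#' ds
simulate_batch <- function(preset, noise, n_points = 40, dt = 0.5,
                           gas = gas_conditions(), reactor_volume = 1,
                           strain = "synthetic") {
  stopifnot(inherits(preset, "strain_preset"), inherits(noise, "noise_model"),
            n_points >= 4, dt > 0, reactor_volume > 0)
  times <- (seq_len(n_points) - 1) * dt
  t_dep <- depletion_time(preset)
  sample_idx <- which(times <= t_dep)
  if (length(sample_idx) < 4) {
    stop("glucose depleted before the 4th sampling point (t_dep = ",
         signif(t_dep, 4), " h); shorten dt or lower the uptake rate",
         call. = FALSE)
  }
  traj <- preset_trajectory(preset, times)

  # gas-phase CO2 release in mol/h; exponential decay after depletion
  release <- (1 - preset$co2_retention) * preset$pi_co2 *
    traj$biomass * reactor_volume / 1000
  after <- times > t_dep
  if (any(after)) {
    x_dep <- preset$x0 * exp(preset$mu * (t_dep - preset$lag_h))
    r_dep <- (1 - preset$co2_retention) * preset$pi_co2 * x_dep *
      reactor_volume / 1000
    release[after] <- r_dep * exp(-preset$mu * (times[after] - t_dep))
  }

  # invert the gas balance at RQ = 1: total molar flow is conserved, the
  # inert fraction is unchanged, CO2 release adds to / O2 uptake subtracts
  # from the respective inlet molar flows
  q_mol <- gas$flow_m3_h * gas$pressure_pa /
    (gas$gas_constant * gas$temperature_k)
  phi_co2_out <- gas$phi_co2_in + 100 * release / q_mol
  phi_o2_out <- gas$phi_o2_in - 100 * release / q_mol
  if (any(phi_o2_out < 0)) {
    stop("simulated O2 demand exceeds the O2 supplied by the inlet flow; ",
         "increase the gas flow or reactor headroom", call. = FALSE)
  }

  withr::with_seed(noise$seed, {
    # noise is drawn at the configured magnitude (exactly zero when off);
    # recorded sds are floored at a tiny positive value so noiseless
    # datasets remain valid weighted-fit inputs
    sd_floor <- function(sd, scale) pmax(sd, 1e-8 * max(scale, 1))
    b_true <- traj$biomass[sample_idx]
    b_noise_sd <- noise$rel_sd_biomass * b_true
    g_true <- traj$glucose[sample_idx]
    g_noise_sd <- if (noise$rel_sd_glucose > 0) {
      pmax(noise$rel_sd_glucose * abs(g_true), 0.05)
    } else {
      rep(0, length(g_true))
    }
    gas_noise_sd <- rep(noise$abs_sd_gas, n_points)

    biomass <- measurement_series(
      tibble::tibble(time_h = times[sample_idx],
                     value = b_true +
                       stats::rnorm(length(b_true), 0, b_noise_sd),
                     sd = sd_floor(b_noise_sd, max(b_true))),
      "biomass_cdw")
    glucose <- measurement_series(
      tibble::tibble(time_h = times[sample_idx],
                     value = g_true +
                       stats::rnorm(length(g_true), 0, g_noise_sd),
                     sd = sd_floor(g_noise_sd, max(g_true))),
      "glucose")
    offgas_o2 <- measurement_series(
      tibble::tibble(time_h = times,
                     value = phi_o2_out + stats::rnorm(n_points, 0, gas_noise_sd),
                     sd = sd_floor(gas_noise_sd, 1e-4)),
      "o2_out")
    offgas_co2 <- measurement_series(
      tibble::tibble(time_h = times,
                     value = phi_co2_out + stats::rnorm(n_points, 0, gas_noise_sd),
                     sd = sd_floor(gas_noise_sd, 1e-4)),
      "co2_out")
    batch_dataset(biomass, glucose, offgas_o2, offgas_co2,
                  gas = gas, reactor_volume = reactor_volume, strain = strain)
  })
}

#' Analytic instantaneous carbon balance of a preset
#'
#' Closed-form carbon balance implied by a strain preset's true rates:
#' `theta = (mu * omega_c / M_C + pi_co2_eff) / (6 * pi_glc)`, where
#' `pi_co2_eff` is the full production rate, or the gas-phase share
#' `(1 - rho) * pi_co2` when `measured_only = TRUE` (what the off-gas
#' analyzer can see).
#'
#' @param preset A [strain_preset()].
#' @param cp [carbon_params()].
#' @param measured_only If `TRUE`, discount the dissolved/retained CO2 share.
#' @return Dimensionless carbon balance.
#' @export
analytic_theta <- function(preset, cp = carbon_params(),
                           measured_only = FALSE) {
  stopifnot(inherits(preset, "strain_preset"), inherits(cp, "carbon_params"))
  pi_co2_eff <- if (measured_only) {
    (1 - preset$co2_retention) * preset$pi_co2
  } else {
    preset$pi_co2
  }
  (preset$mu * cp$omega_c / cp$m_c + pi_co2_eff) / (6 * preset$pi_glc)
}
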