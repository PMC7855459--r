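# Instantaneous carbon balance: carbon flowing into biomass and CO2 relative
# to the carbon taken up as glucose, evaluated from specific rates.

#' Instantaneous carbon balance
#'
#' Balances the specific rates of carbon uptake and carbon flow into sinks at
#' a time point during exponential growth:
#' `theta = (mu * omega_c / M_C + pi_co2) / (6 * pi_glc)`.
#' Biomass (carbon content `omega_c`, gC/gCDW) and CO2 are the only sinks;
#' glucose carries 6 carbon atoms per molecule. `theta < 1` flags carbon that
#' reaches neither sink — in practice largely CO2 dissolved as bicarbonate
#' and therefore invisible to the off-gas analyzer.
#'
#' @param mu Specific growth rate, 1/h.
#' @param pi_glc Specific glucose uptake rate, mmol/gCDW/h (> 0).
#' @param pi_co2 Specific CO2 formation rate, mmol/gCDW/h.
#' @param cp [carbon_params()].
#'
#' @return Object of class `carbon_balance` with `theta`, the three
#'   carbon-equivalent rates (mmolC/gCDW/h) and `sd_theta` (NA until
#'   [propagate_theta_error()] is applied).
#' @export
#' @examples
#' instantaneous_theta(mu = 0.45, pi_glc = 4.82, pi_co2 = 6.94)
instantaneous_theta <- function(mu, pi_glc, pi_co2, cp = carbon_params()) {
  stopifnot(inherits(cp, "carbon_params"), mu >= 0, pi_co2 >= 0)
  if (pi_glc <= 0) stop("pi_glc must be positive", call. = FALSE)
  biomass_rate <- mu * cp$omega_c / cp$m_c
  uptake_rate <- 6 * pi_glc
  structure(
    list(theta = (biomass_rate + pi_co2) / uptake_rate,
         sd_theta = NA_real_,
         biomass_carbon_rate = biomass_rate,
         co2_carbon_rate = pi_co2,
         uptake_carbon_rate = uptake_rate,
         inputs = list(mu = mu, pi_glc = pi_glc, pi_co2 = pi_co2, cp = cp)),
    class = "carbon_balance"
  )
}

#' Gaussian error propagation for the carbon balance
#'
#' First-order propagation of independent standard errors of `mu`, `pi_glc`,
#' `pi_co2` and `omega_c` through the carbon balance, with analytic partial
#' derivatives evaluated at the point estimate. No covariances are assumed
#' (none are generally available), which tends to give slightly larger errors
#' than propagation with fitted parameter covariances would.
#'
#' @inheritParams instantaneous_theta
#' @param sd_mu,sd_pi_glc,sd_pi_co2 Standard errors of the rates (>= 0).
#' @return Standard error of theta.
#' @export
propagate_theta_error <- function(mu, pi_glc, pi_co2,
                                  sd_mu, sd_pi_glc, sd_pi_co2,
                                  cp = carbon_params()) {
  stopifnot(pi_glc > 0, sd_mu >= 0, sd_pi_glc >= 0, sd_pi_co2 >= 0)
  theta <- (mu * cp$omega_c / cp$m_c + pi_co2) / (6 * pi_glc)
  d_mu <- cp$omega_c / (cp$m_c * 6 * pi_glc)
  d_co2 <- 1 / (6 * pi_glc)
  d_glc <- -theta / pi_glc
  d_omega <- mu / (cp$m_c * 6 * pi_glc)
  sqrt((d_mu * sd_mu)^2 + (d_co2 * sd_pi_co2)^2 +
         (d_glc * sd_pi_glc)^2 + (d_omega * cp$sd_omega_c)^2)
}

#' Carbon balance with propagated error
#'
#' Convenience constructor combining [instantaneous_theta()] and
#' [propagate_theta_error()].
#'
#' @inheritParams propagate_theta_error
#' @return A `carbon_balance` with `sd_theta` set.
#' @export
carbon_balance <- function(mu, pi_glc, pi_co2,
                           sd_mu = 0, sd_pi_glc = 0, sd_pi_co2 = 0,
                           cp = carbon_params()) {
  cb <- instantaneous_theta(mu, pi_glc, pi_co2, cp)
  cb$sd_theta <- propagate_theta_error(mu, pi_glc, pi_co2,
                                       sd_mu, sd_pi_glc, sd_pi_co2, cp)
  cb
}

#' Decompose carbon uptake into sinks
#'
#' Fractions of the carbon-uptake rate flowing into biomass, into measured
#' CO2, and into the unaccounted gap: `biomass + co2 = theta`, `gap = 1 -
#' theta`. This is the stacked-bar decomposition used to visualize carbon
#' recovery per strain.
#'
#' @param cb A `carbon_balance`.
#' @return Named numeric vector `(biomass_fraction, co2_fraction,
#'   gap_fraction)`.
#' @export
sink_decomposition <- function(cb) {
  stopifnot(inherits(cb, "carbon_balance"))
  c(biomass_fraction = cb$biomass_carbon_rate / cb$uptake_carbon_rate,
    co2_fraction = cb$co2_carbon_rate / cb$uptake_carbon_rate,
    gap_fraction = 1 - cb$theta)
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat(sprintf("<carbon_balance> theta = %.4g", x$theta))
  if (!is.na(x$sd_theta)) cat(sprintf(" +/- %.3g", x$sd_theta))
  cat("\n")
  s <- sink_decomposition(x)
  cat(sprintf("  biomass %.1f %% + CO2 %.1f %% of uptake carbon; gap %.1f %%\n",
              100 * s[1], 100 * s[2], 100 * s[3]))
  invisible(x)
}

#' @rdname instantaneous_theta
#' @param x A `carbon_balance`.
#' @param ... Unused.
#' @export
tidy.carbon_balance <- function(x, ...) {
  s <- sink_decomposition(x)
  tibble::tibble(
    sink = c("biomass", "co2", "gap"),
    carbon_rate = c(x$biomass_carbon_rate, x$co2_carbon_rate,
                    x$uptake_carbon_rate * s[["gap_fraction"]]),
    fraction_of_uptake = unname(s)
  )
}

#' @rdname instantaneous_theta
#' @export
glance.carbon_balance <- function(x, ...) {
  tibble::tibble(theta = x$theta, sd_theta = x$sd_theta,
                 uptake_carbon_rate = x$uptake_carbon_rate)
}

#' Published specific rates of the anaplerosis strain panel
#'
#' Batch-bioreactor specific growth, glucose-uptake and CO2-formation rates
#' (with their reported confidence half-widths) for *C. glutamicum* ATCC
#' 13032 and eight anaplerotic deletion mutants, together with the published
#' instantaneous carbon balance per strain. Shipped as a plain-text table so
#' the carbon-balance arithmetic can be checked against published values.
#'
#' @return Tibble with columns `strain`, `mu`, `mu_err`, `pi_glc`,
#'   `pi_glc_err`, `pi_co2`, `pi_co2_err` (rates in 1/h and mmol/gCDW/h),
#'   `theta_published`, `theta_err_published`.
#' @export
#' @examples
#' rates <- anaplerosis_rates()
#' with(rates[1, ], instantaneous_theta(mu, pi_glc, pi_co2))
anaplerosis_rates <- function() {
  path <- system.file("extdata", "anaplerosis_rates.csv",
                      package = "batchphys", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
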