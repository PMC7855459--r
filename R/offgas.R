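# Gas-phase CO2 balancing: total and biomass-specific CO2 formation rates
# from inlet/outlet gas compositions.

#' Total CO2 formation rate from the reactor gas balance
#'
#' Balances the gas phase using the inert-gas (N2 + trace) fraction, which
#' passes through the reactor unchanged:
#' `pi_co2_tot = F*p/(R*T) * [ (100 - phi_o2_in - phi_co2_in) /
#' (100 - phi_o2_out - phi_co2_out) * phi_co2_out/100 - phi_co2_in/100 ]`
#' with `F` in m^3/h, `p` in Pa, `T` in K. Vectorized over the outlet
#' fractions.
#'
#' @param gas [gas_conditions()].
#' @param phi_o2_out Outlet O2 volume fraction(s), vol%.
#' @param phi_co2_out Outlet CO2 volume fraction(s), vol%.
#' @return CO2 formation rate(s), mol/h. Negative values indicate outlet CO2
#'   below inlet CO2.
#' @export
#' @examples
#' g <- gas_conditions(flow_m3_h = 0.06, pressure_pa = 101325,
#'                     temperature_k = 298.15)
#' co2_formation_rate(g, phi_o2_out = 19.5, phi_co2_out = 1.5)
co2_formation_rate <- function(gas, phi_o2_out, phi_co2_out) {
  stopifnot(inherits(gas, "gas_conditions"),
            all(phi_o2_out >= 0), all(phi_co2_out >= 0),
            all(phi_o2_out < 100), all(phi_co2_out < 100))
  denom <- 100 - phi_o2_out - phi_co2_out
  if (any(denom <= 0)) {
    stop("outlet O2 + CO2 fractions reach 100 vol%: nonphysical composition",
         call. = FALSE)
  }
  q_mol <- gas$flow_m3_h * gas$pressure_pa /
    (gas$gas_constant * gas$temperature_k)
  inert_in <- 100 - gas$phi_o2_in - gas$phi_co2_in
  q_mol * (inert_in / denom * phi_co2_out / 100 - gas$phi_co2_in / 100)
}

#' Standard error of the gas-balance CO2 rate
#'
#' First-order Gaussian propagation of independent analyzer errors on the
#' outlet O2 and CO2 fractions through the gas balance; partial derivatives
#' are analytic. Vectorized.
#'
#' @inheritParams co2_formation_rate
#' @param sd_phi_o2,sd_phi_co2 Analyzer standard deviations, vol%.
#' @return Standard error(s) of the rate, mol/h.
#' @export
co2_formation_rate_sd <- function(gas, phi_o2_out, phi_co2_out,
                                  sd_phi_o2, sd_phi_co2) {
  denom <- 100 - phi_o2_out - phi_co2_out
  stopifnot(all(denom > 0), all(sd_phi_o2 >= 0), all(sd_phi_co2 >= 0))
  q_mol <- gas$flow_m3_h * gas$pressure_pa /
    (gas$gas_constant * gas$temperature_k)
  inert_in <- 100 - gas$phi_o2_in - gas$phi_co2_in
  d_co2 <- q_mol * inert_in / 100 * (100 - phi_o2_out) / denom^2
  d_o2 <- q_mol * inert_in / 100 * phi_co2_out / denom^2
  sqrt((d_co2 * sd_phi_co2)^2 + (d_o2 * sd_phi_o2)^2)
}

#' Biomass-specific CO2 formation rate series
#'
#' Divides the total CO2 formation rate by the total biomass predicted by the
#' fitted growth model (`X(t) * V`), converting mol/h to mmol per biomass
#' unit per h. The fitted model is used rather than raw biomass points so the
#' specific rate is not corrupted by biomass measurement noise. The scalar
#' summary `pi_co2_mean` is the arithmetic mean over the points inside the
#' exponential-phase window.
#'
#' @param times Times of the total-rate series, h.
#' @param pi_co2_tot Total CO2 formation rates, mol/h.
#' @param fit A [fit_rates()] result.
#' @param reactor_volume Working volume, L.
#' @param window A [phase_window()] over which the mean is taken.
#' @param sd_pi_co2_tot Optional standard errors of `pi_co2_tot` (mol/h);
#'   when given, the standard error of the window mean is propagated.
#'
#' @return Object of class `gas_balance`: tibble of `time_h`, `pi_co2_tot`,
#'   `pi_co2_specific` plus the window mean (and its sd, if computable).
#' @export
specific_co2_rate <- function(times, pi_co2_tot, fit, reactor_volume, window,
                              sd_pi_co2_tot = NULL) {
  stopifnot(length(times) == length(pi_co2_tot), reactor_volume > 0,
            inherits(fit, "rate_fit"), inherits(window, "phase_window"))
  x <- model_biomass(fit$x0, fit$mu, times)
  if (any(x <= 0)) stop("zero biomass in the specific-rate division",
                        call. = FALSE)
  specific <- 1000 * pi_co2_tot / (x * reactor_volume)
  in_win <- times >= window$t_start & times <= window$t_end
  if (!any(in_win)) stop("no gas points inside the window", call. = FALSE)
  series <- tibble::tibble(time_h = times, pi_co2_tot = pi_co2_tot,
                           pi_co2_specific = specific, in_window = in_win)
  sd_mean <- NA_real_
  if (!is.null(sd_pi_co2_tot)) {
    sd_specific <- 1000 * sd_pi_co2_tot / (x * reactor_volume)
    series$sd_pi_co2_specific <- sd_specific
    sd_mean <- sqrt(sum(sd_specific[in_win]^2)) / sum(in_win)
  }
  structure(
    list(series = series,
         pi_co2_mean = mean(specific[in_win]),
         sd_pi_co2_mean = sd_mean,
         unit = rate_fit_units(fit)[["pi_glc"]],
         negative_rates = any(pi_co2_tot < 0)),
    class = "gas_balance"
  )
}

#' Gas balance of a batch dataset
#'
#' Convenience wrapper: aligns the off-gas O2 and CO2 series of a dataset on
#' their common times, computes the total CO2 formation rate at each time via
#' [co2_formation_rate()], propagates the recorded analyzer sds, and derives
#' the biomass-specific series via [specific_co2_rate()].
#'
#' @param ds A [batch_dataset()].
#' @param fit A [fit_rates()] result for `ds`.
#' @param window A [phase_window()].
#' @return A `gas_balance` (see [specific_co2_rate()]).
#' @export
offgas_balance <- function(ds, fit, window) {
  o2 <- ds$offgas_o2
  co2 <- ds$offgas_co2
  common <- intersect(o2$time_h, co2$time_h)
  if (length(common) < 2) {
    stop("off-gas O2 and CO2 series share fewer than 2 time points",
         call. = FALSE)
  }
  o2 <- o2[o2$time_h %in% common, ]
  co2 <- co2[co2$time_h %in% common, ]
  tot <- co2_formation_rate(ds$gas, o2$value, co2$value)
  sd_tot <- co2_formation_rate_sd(ds$gas, o2$value, co2$value,
                                  o2$sd, co2$sd)
  specific_co2_rate(co2$time_h, tot, fit, ds$reactor_volume, window,
                    sd_pi_co2_tot = sd_tot)
}

#' @export
print.gas_balance <- function(x, ...) {
  cat(sprintf("<gas_balance> %d time points, window mean pi_CO2 = %.4g %s",
              nrow(x$series), x$pi_co2_mean, x$unit))
  if (!is.na(x$sd_pi_co2_mean)) cat(sprintf(" (sd %.3g)", x$sd_pi_co2_mean))
  cat("\n")
  if (x$negative_rates) {
    cat("  note: some total rates are negative (outlet CO2 below inlet)\n")
  }
  invisible(x)
}

#' @rdname specific_co2_rate
#' @param x A `gas_balance`.
#' @param ... Unused.
#' @export
tidy.gas_balance <- function(x, ...) {
  x$series
}

#' @rdname specific_co2_rate
#' @export
glance.gas_balance <- function(x, ...) {
  tibble::tibble(pi_co2_mean = x$pi_co2_mean,
                 sd_pi_co2_mean = x$sd_pi_co2_mean,
                 unit = x$unit,
                 n_points = nrow(x$series),
                 negative_rates = x$negative_rates)
}
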