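# Shared domain types: measurement series, gas conditions, carbon parameters,
# and the batch dataset container that every pipeline stage consumes.

QUANTITY_TAGS <- c(
  biomass_bv  = "µL/mL",
  biomass_cdw = "g/L",
  glucose     = "mmol/L",
  o2_out      = "vol%",
  co2_out     = "vol%"
)

#' Construct a measurement series
#'
#' A measurement series is a tibble of time-stamped observations of one
#' quantity, each with its own standard deviation. Times are hours since
#' inoculation and must be strictly increasing; standard deviations must be
#' strictly positive because downstream fits weight residuals by `1/sd^2`.
#'
#' @param data Data frame with columns `time_h`, `value` and optionally `sd`.
#' @param quantity One of `"biomass_bv"` (µL/mL), `"biomass_cdw"` (g/L),
#'   `"glucose"` (mmol/L), `"o2_out"` (vol%), `"co2_out"` (vol%).
#' @param sd Per-point standard deviations, recycled; used when `data` has no
#'   `sd` column.
#' @param rel_sd Relative standard deviation applied to `value` when neither
#'   an `sd` column nor `sd` is given.
#'
#' @return A tibble of class `measurement_series` with columns `time_h`,
#'   `value`, `sd` and attributes `quantity` and `unit`.
#' @export
#' @examples
#' measurement_series(data.frame(time_h = 0:3, value = c(1, 2, 4, 8)),
#'                    "biomass_cdw", rel_sd = 0.05)
measurement_series <- function(data, quantity, sd = NULL, rel_sd = NULL) {
  quantity <- match.arg(quantity, names(QUANTITY_TAGS))
  stopifnot(is.data.frame(data), all(c("time_h", "value") %in% names(data)))
  out <- tibble::tibble(
    time_h = as.numeric(data$time_h),
    value = as.numeric(data$value)
  )
  if (!is.null(sd)) {
    out$sd <- rep_len(as.numeric(sd), nrow(out))
  } else if ("sd" %in% names(data)) {
    out$sd <- as.numeric(data$sd)
  } else if (!is.null(rel_sd)) {
    out$sd <- rel_sd * abs(out$value)
  } else {
    stop("no standard deviations: supply an `sd` column, `sd`, or `rel_sd`",
         call. = FALSE)
  }
  issues <- series_issues(out, quantity)
  if (length(issues) > 0) {
    stop("invalid measurement series (", quantity, "): ",
         paste(issues, collapse = "; "), call. = FALSE)
  }
  structure(out,
            quantity = quantity,
            unit = unname(QUANTITY_TAGS[quantity]),
            class = c("measurement_series", class(out)))
}

series_issues <- function(x, quantity = attr(x, "quantity")) {
  issues <- character()
  tag <- if (is.null(quantity)) "series" else quantity
  if (!all(c("time_h", "value", "sd") %in% names(x))) {
    return(paste0(tag, ": missing one of columns time_h/value/sd"))
  }
  if (nrow(x) < 2) {
    issues <- c(issues, paste0(tag, ": fewer than 2 points"))
  }
  if (anyNA(x$time_h) || anyNA(x$value) || anyNA(x$sd)) {
    issues <- c(issues, paste0(tag, ": missing values present"))
  }
  if (any(x$time_h < 0, na.rm = TRUE)) {
    issues <- c(issues, paste0(tag, ": negative times"))
  }
  if (nrow(x) >= 2 && any(diff(x$time_h) <= 0, na.rm = TRUE)) {
    issues <- c(issues, paste0(tag, ": times not strictly increasing"))
  }
  if (any(x$sd <= 0, na.rm = TRUE)) {
    issues <- c(issues, paste0(tag, ": non-positive standard deviation"))
  }
  issues
}

#' Gas-phase conditions of a cultivation
#'
#' Inlet gas composition, flow and the physical state used by the gas-phase
#' CO2 balance. Defaults for pressure and temperature are mass-flow-controller
#' norm conditions (101325 Pa, 273.15 K); both are configurable because the
#' molar inflow `F*p/(R*T)` scales every gas-balance result linearly.
#'
#' @param flow_m3_h Inlet air flow in m^3/h.
#' @param pressure_pa Pressure in Pa.
#' @param temperature_k Temperature in K.
#' @param phi_o2_in Inlet O2 volume fraction, vol%.
#' @param phi_co2_in Inlet CO2 volume fraction, vol%.
#'
#' @return A list of class `gas_conditions` (gas constant fixed at
#'   8.314 J/(mol K)).
#' @export
gas_conditions <- function(flow_m3_h = 0.06,
                           pressure_pa = 101325,
                           temperature_k = 273.15,
                           phi_o2_in = 20.95,
                           phi_co2_in = 0.04) {
  stopifnot(flow_m3_h > 0, pressure_pa > 0, temperature_k > 0,
            phi_o2_in >= 0, phi_co2_in >= 0,
            phi_o2_in + phi_co2_in < 100)
  structure(
    list(flow_m3_h = flow_m3_h, pressure_pa = pressure_pa,
         temperature_k = temperature_k, gas_constant = 8.314,
         phi_o2_in = phi_o2_in, phi_co2_in = phi_co2_in),
    class = "gas_conditions"
  )
}

#' Carbon-balance parameters
#'
#' Carbon mass fraction of dry biomass and its assumed standard error.
#' Literature values for *Corynebacterium glutamicum* span roughly
#' 0.41--0.51 gC/gCDW; the default 0.45 +/- 0.05 covers that interval.
#' The molar mass of carbon is fixed at 0.012011 g/mmol.
#'
#' @param omega_c Carbon mass fraction of biomass, gC/gCDW.
#' @param sd_omega_c Standard error of `omega_c`, gC/gCDW.
#'
#' @return A list of class `carbon_params`.
#' @export
carbon_params <- function(omega_c = 0.45, sd_omega_c = 0.05) {
  stopifnot(omega_c > 0, omega_c < 1, sd_omega_c >= 0)
  structure(
    list(omega_c = omega_c, sd_omega_c = sd_omega_c, m_c = 0.012011),
    class = "carbon_params"
  )
}

#' Assemble a batch cultivation dataset
#'
#' Bundles the measured time series of one batch reactor (biomass, residual
#' glucose, off-gas O2 and CO2) with its gas conditions and working volume.
#'
#' @param biomass `measurement_series` tagged `biomass_bv` or `biomass_cdw`.
#' @param glucose `measurement_series` tagged `glucose`; its first value plays
#'   the initial substrate concentration absorbed into the fit constant `C`.
#' @param offgas_o2,offgas_co2 Off-gas `measurement_series` in vol%.
#' @param gas `gas_conditions`.
#' @param reactor_volume Working volume in L.
#' @param strain Free-text strain label.
#'
#' @return A list of class `batch_dataset`.
#' @seealso [validate_dataset()]
#' @export
batch_dataset <- function(biomass, glucose, offgas_o2, offgas_co2,
                          gas, reactor_volume, strain = "unnamed") {
  ds <- structure(
    list(biomass = biomass, glucose = glucose,
         offgas_o2 = offgas_o2, offgas_co2 = offgas_co2,
         gas = gas, reactor_volume = reactor_volume, strain = strain),
    class = "batch_dataset"
  )
  issues <- validate_dataset(ds)
  if (length(issues) > 0) {
    stop("invalid batch dataset: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  ds
}

#' Validate a batch dataset
#'
#' Checks every container invariant and returns one human-readable issue per
#' violation instead of raising, so callers can report all problems at once.
#' The input is never modified.
#'
#' @param ds A `batch_dataset` (possibly constructed by hand).
#' @return Character vector of issues; empty when all invariants hold.
#' @export
validate_dataset <- function(ds) {
  issues <- character()
  for (nm in c("biomass", "glucose", "offgas_o2", "offgas_co2")) {
    s <- ds[[nm]]
    if (is.null(s) || !is.data.frame(s)) {
      issues <- c(issues, paste0(nm, ": missing or not a data frame"))
      next
    }
    issues <- c(issues, series_issues(s, quantity = nm))
  }
  expected <- list(biomass = c("biomass_bv", "biomass_cdw"),
                   glucose = "glucose", offgas_o2 = "o2_out",
                   offgas_co2 = "co2_out")
  for (nm in names(expected)) {
    q <- attr(ds[[nm]], "quantity")
    if (!is.null(q) && !q %in% expected[[nm]]) {
      issues <- c(issues, paste0(nm, ": unexpected quantity tag '", q, "'"))
    }
  }
  if (is.null(ds$reactor_volume) || !is.numeric(ds$reactor_volume) ||
      ds$reactor_volume <= 0) {
    issues <- c(issues, "reactor_volume: must be a positive number (L)")
  }
  g <- ds$gas
  if (is.null(g) || !inherits(g, "gas_conditions")) {
    issues <- c(issues, "gas: missing gas_conditions")
  }
  b <- ds$biomass; gl <- ds$glucose
  if (is.data.frame(b) && is.data.frame(gl) &&
      nrow(b) > 0 && nrow(gl) > 0 &&
      (max(b$time_h) < min(gl$time_h) || max(gl$time_h) < min(b$time_h))) {
    issues <- c(issues, "biomass and glucose series do not overlap in time")
  }
  issues
}

#' @export
print.batch_dataset <- function(x, ...) {
  cat("<batch_dataset> strain:", x$strain, "\n")
  cat("  reactor volume:", x$reactor_volume, "L\n")
  for (nm in c("biomass", "glucose", "offgas_o2", "offgas_co2")) {
    s <- x[[nm]]
    cat(sprintf("  %-10s %3d points, %s [%s], t = %.2f..%.2f h\n",
                nm, nrow(s), attr(s, "quantity"), attr(s, "unit"),
                min(s$time_h), max(s$time_h)))
  }
  invisible(x)
}
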