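# Exponential-phase window detection from the exhaust-gas CO2 trace.

# centered moving average with half-width h, window shrunk at the edges
moving_average <- function(x, halfwidth) {
  n <- length(x)
  if (halfwidth <= 0) return(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - halfwidth)
    hi <- min(n, i + halfwidth)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Detect the exponential-phase fitting window
#'
#' The end of the exponential phase is taken as the peak of the (smoothed)
#' CO2 volume fraction in the exhaust gas: once the substrate runs out, CO2
#' evolution collapses, so the trace peaks at depletion. The window start is
#' the earliest time at which biomass exceeds `start_threshold_rel` times the
#' biomass at the window end, which excludes the lag phase. Ties in the
#' smoothed maximum resolve to the earliest time, so post-exponential decline
#' is never included.
#'
#' @param co2_out `measurement_series` of outlet CO2 (vol%), >= 5 points.
#' @param biomass Biomass `measurement_series`.
#' @param smooth_halfwidth Half-width (in samples) of the centered moving
#'   average applied to the CO2 trace before locating the peak.
#' @param start_threshold_rel Window start rule: fraction of end-of-window
#'   biomass that must be exceeded.
#' @param glucose Optional glucose `measurement_series`; when given, the
#'   window is widened so at least 4 glucose points fall inside it.
#'
#' @return A list of class `phase_window` with `t_start`, `t_end`,
#'   `peak_co2_volpct` and `n_points_in_window` (biomass points).
#' @export
detect_window <- function(co2_out, biomass, smooth_halfwidth = 2,
                          start_threshold_rel = 0.05, glucose = NULL) {
  stopifnot(is.data.frame(co2_out), nrow(co2_out) >= 5,
            is.data.frame(biomass), nrow(biomass) >= 4,
            smooth_halfwidth >= 0, start_threshold_rel > 0,
            start_threshold_rel < 1)
  sm <- moving_average(co2_out$value, smooth_halfwidth)
  peak <- which.max(sm)  # which.max returns the earliest tie
  if (peak == length(sm)) {
    stop("CO2 peak falls on the last sample: the culture has not finished; ",
         "window end undefined", call. = FALSE)
  }
  t_end <- co2_out$time_h[peak]

  x_end <- stats::approx(biomass$time_h, biomass$value, xout = t_end,
                         rule = 2)$y
  above <- biomass$value > start_threshold_rel * x_end & biomass$time_h <= t_end
  if (!any(above)) {
    stop("no biomass point exceeds the start threshold before the CO2 peak",
         call. = FALSE)
  }
  t_start <- min(biomass$time_h[above])

  widen_for <- function(series, t_start) {
    idx <- series$time_h <= t_end
    if (sum(series$time_h >= t_start & idx) < 4) {
      tt <- sort(series$time_h[idx], decreasing = TRUE)
      if (length(tt) < 4) {
        stop("fewer than 4 points before the CO2 peak; window too short",
             call. = FALSE)
      }
      t_start <- min(t_start, tt[4])
    }
    t_start
  }
  t_start <- widen_for(biomass, t_start)
  if (!is.null(glucose)) t_start <- widen_for(glucose, t_start)

  n_in <- sum(biomass$time_h >= t_start & biomass$time_h <= t_end)
  structure(
    list(t_start = t_start, t_end = t_end,
         peak_co2_volpct = sm[peak], n_points_in_window = n_in),
    class = "phase_window"
  )
}

#' Build a phase window by hand
#'
#' Bypass CO2-peak detection when the fitting window is known, e.g. chosen by
#' eye or fixed by the experimental design.
#'
#' @param t_start,t_end Window bounds, h (`t_start < t_end`).
#' @param peak_co2_volpct Optional CO2 peak value to record, vol%.
#' @param n_points_in_window Optional point count to record.
#' @return A `phase_window`.
#' @export
phase_window <- function(t_start, t_end, peak_co2_volpct = NA_real_,
                         n_points_in_window = NA_integer_) {
  stopifnot(t_start < t_end)
  structure(
    list(t_start = t_start, t_end = t_end,
         peak_co2_volpct = peak_co2_volpct,
         n_points_in_window = n_points_in_window),
    class = "phase_window"
  )
}

#' @export
print.phase_window <- function(x, ...) {
  cat(sprintf(
    "<phase_window> %.3g .. %.3g h (peak CO2 %.3g vol%%, %s biomass points)\n",
    x$t_start, x$t_end, x$peak_co2_volpct,
    ifelse(is.na(x$n_points_in_window), "?", x$n_points_in_window)))
  invisible(x)
}
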