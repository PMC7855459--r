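# Joint variance-weighted fit of the exponential-growth and glucose-depletion
# models over the exponential-phase window.

#' Exponential biomass model
#'
#' `X(t) = X0 * exp(mu * t)`, in the unit of the biomass series (g/L for CDW,
#' µL/mL for biovolume).
#'
#' @param x0 Initial biomass at t = 0.
#' @param mu Specific growth rate, 1/h.
#' @param t Time(s), h.
#' @return Biomass concentration(s).
#' @export
model_biomass <- function(x0, mu, t) {
  stopifnot(x0 > 0)
  x0 * exp(mu * t)
}

#' Glucose depletion model
#'
#' Integrating a constant specific uptake rate over exponential growth gives
#' `c_GLC(t) = C - (pi_glc / mu) * X0 * exp(mu * t)`; the constant `C` absorbs
#' the integration constant and the initial substrate concentration.
#'
#' @param c_const Lumped constant `C`, mmol/L.
#' @param pi_glc Specific glucose uptake rate, mmol per biomass unit per h.
#' @param mu Specific growth rate, 1/h (> 0).
#' @param x0 Initial biomass.
#' @param t Time(s), h.
#' @return Glucose concentration(s), mmol/L.
#' @export
model_glucose <- function(c_const, pi_glc, mu, x0, t) {
  stopifnot(mu > 0)
  c_const - (pi_glc / mu) * x0 * exp(mu * t)
}

# weighted residual vector over the fitting window
rate_residuals <- function(par, b, g) {
  x0 <- par[1]; mu <- par[2]; pi_glc <- par[3]; c_const <- par[4]
  c((b$value - x0 * exp(mu * b$time_h)) / b$sd,
    (g$value - (c_const - (pi_glc / mu) * x0 * exp(mu * g$time_h))) / g$sd)
}

# closed-form starting values: log-linear regression for (X0, mu), a
# mass-balance ratio for pi_glc, and the first glucose observation for C
rate_fit_start <- function(b, g) {
  pos <- b$value > 0
  if (sum(pos) < 2) stop("too few positive biomass values", call. = FALSE)
  ll <- stats::lm(log(value) ~ time_h, data = b[pos, ])
  mu0 <- max(unname(stats::coef(ll)["time_h"]), 1e-3)
  x00 <- exp(unname(stats::coef(ll)["(Intercept)"]))
  dx <- x00 * (exp(mu0 * max(g$time_h)) - exp(mu0 * min(g$time_h)))
  pi0 <- max((g$value[1] - g$value[nrow(g)]) * mu0 / dx, 1e-6)
  c0 <- g$value[1] + (pi0 / mu0) * x00 * exp(mu0 * g$time_h[1])
  c(x0 = x00, mu = mu0, pi_glc = pi0, c_const = c0)
}

#' Jointly fit growth and glucose-uptake rates
#'
#' Minimizes the variance-weighted sum of squared residuals of the biomass
#' and glucose models over all points inside the exponential-phase window,
#' with box constraints `X0 > 0`, `mu > 0`, `pi_glc >= 0`. Weights are
#' `1/sd^2` per point. Optimization is constrained Levenberg--Marquardt
#' nonlinear least squares, warm-started from closed-form estimates
#' (log-linear regression of biomass; a window mass balance for the uptake
#' rate). Deterministic given data and starting values.
#'
#' @param ds A [batch_dataset()].
#' @param window A [phase_window()] (see [detect_window()]).
#' @param start Optional named starting vector `(x0, mu, pi_glc, c_const)`;
#'   defaults to the closed-form starts.
#' @param max_iter Iteration cap; exceeding it without meeting the relative
#'   tolerance (1e-10) is an error, not a silent result.
#'
#' @return Object of class `rate_fit` with the four parameter estimates, the
#'   achieved weighted SSE, the window, point counts and the biomass unit of
#'   the specific-rate denominator.
#' @export
#' @examples
#' ds <- simulate_batch(strain_preset(), noise_model(seed = 3),
#'                      n_points = 40, dt = 0.5)
#' w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
#' fit_rates(ds, w)
fit_rates <- function(ds, window, start = NULL, max_iter = 500) {
  stopifnot(inherits(window, "phase_window"))
  issues <- validate_dataset(ds)
  if (length(issues) > 0) {
    stop("invalid dataset: ", paste(issues, collapse = "; "), call. = FALSE)
  }
  in_win <- function(s) {
    s[s$time_h >= window$t_start & s$time_h <= window$t_end, , drop = FALSE]
  }
  b <- in_win(ds$biomass)
  g <- in_win(ds$glucose)
  if (nrow(b) < 4 || nrow(g) < 4) {
    stop("need >= 4 biomass and >= 4 glucose points inside the window (have ",
         nrow(b), " and ", nrow(g), ")", call. = FALSE)
  }
  if (is.null(start)) start <- rate_fit_start(b, g)
  stopifnot(length(start) == 4)

  lm_fit <- minpack.lm::nls.lm(
    par = start, fn = rate_residuals, b = b, g = g,
    lower = c(1e-12, 1e-12, 0, -Inf),
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-10, gtol = 0)
  )
  if (!lm_fit$info %in% 1:4) {
    stop("rate fit did not converge (nls.lm info = ", lm_fit$info, ": ",
         lm_fit$message, ")", call. = FALSE)
  }
  par <- lm_fit$par
  sse <- sum(rate_residuals(par, b, g)^2)
  start_sse <- sum(rate_residuals(start, b, g)^2)
  if (sse > start_sse + 1e-8 * (1 + start_sse)) {
    stop("optimizer ended above its starting objective; fit rejected",
         call. = FALSE)
  }
  structure(
    list(x0 = unname(par[1]), mu = unname(par[2]), pi_glc = unname(par[3]),
         c_const = unname(par[4]), sse = sse, window = window,
         n_biomass = nrow(b), n_glucose = nrow(g),
         biomass_quantity = attr(ds$biomass, "quantity"),
         biomass_unit = attr(ds$biomass, "unit"),
         data = list(biomass = b, glucose = g),
         convergence = lm_fit$info),
    class = "rate_fit"
  )
}

rate_fit_units <- function(fit) {
  denom <- if (identical(fit$biomass_quantity, "biomass_bv")) {
    "mmol mLBV^-1 h^-1"
  } else {
    "mmol gCDW^-1 h^-1"
  }
  c(x0 = fit$biomass_unit, mu = "h^-1", pi_glc = denom, c_const = "mmol/L")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit>\n")
  cat(sprintf("  X0     = %.6g %s\n", x$x0, x$biomass_unit))
  cat(sprintf("  mu     = %.6g h^-1\n", x$mu))
  cat(sprintf("  pi_glc = %.6g %s\n", x$pi_glc, rate_fit_units(x)[["pi_glc"]]))
  cat(sprintf("  C      = %.6g mmol/L\n", x$c_const))
  cat(sprintf("  weighted SSE %.6g over %d biomass + %d glucose points, window %.3g..%.3g h\n",
              x$sse, x$n_biomass, x$n_glucose,
              x$window$t_start, x$window$t_end))
  invisible(x)
}

#' Tidy a rate fit
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @export
tidy.rate_fit <- function(x, ...) {
  est <- c(x0 = x$x0, mu = x$mu, pi_glc = x$pi_glc, c_const = x$c_const)
  tibble::tibble(term = names(est), estimate = unname(est),
                 unit = unname(rate_fit_units(x)[names(est)]))
}

#' @rdname tidy.rate_fit
#' @return `glance()`: one row with SSE, point counts and window bounds.
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_biomass = x$n_biomass,
                 n_glucose = x$n_glucose,
                 t_start = x$window$t_start, t_end = x$window$t_end,
                 convergence = x$convergence)
}
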