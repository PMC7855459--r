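# Biovolume from particle-size distributions and the linear biovolume <->
# cell-dry-weight calibration used to express biomass in g/L.

#' Biovolume concentration from a particle-size distribution
#'
#' Computes the total cell volume per mL of original culture from a Coulter
#' counter size distribution, assuming spherical cells: each bin contributes
#' `count * (pi/6) * d^3` µm^3, the sum is scaled to µL (1 µm^3 = 1e-9 µL),
#' divided by the analyzed sample volume and multiplied by the dilution
#' factor.
#'
#' @param distribution Data frame with columns `diameter_um` (bin centers,
#'   strictly increasing, > 0) and `count` (particles per bin, >= 0).
#' @param analyzed_volume_ml Volume of diluted sample actually measured, mL.
#' @param dilution_factor Dilution applied before measurement (e.g. 200).
#'
#' @return Biovolume concentration in µL per mL of culture.
#' @export
#' @examples
#' d <- data.frame(diameter_um = c(1.0, 1.5), count = c(2e8, 1e8))
#' biovolume_from_distribution(d, analyzed_volume_ml = 1, dilution_factor = 200)
biovolume_from_distribution <- function(distribution, analyzed_volume_ml,
                                        dilution_factor = 1) {
  stopifnot(is.data.frame(distribution),
            all(c("diameter_um", "count") %in% names(distribution)),
            analyzed_volume_ml > 0, dilution_factor > 0)
  d <- distribution$diameter_um
  n <- distribution$count
  if (length(d) == 0) stop("empty size distribution", call. = FALSE)
  stopifnot(all(d > 0), all(n >= 0))
  if (length(d) > 1 && any(diff(d) <= 0)) {
    stop("diameter bins must be strictly increasing", call. = FALSE)
  }
  vol_um3 <- sum(n * (pi / 6) * d^3)
  dilution_factor * vol_um3 * 1e-9 / analyzed_volume_ml
}

#' Fit a biovolume/cell-dry-weight calibration
#'
#' Ordinary least-squares line `cdw = slope * bv + intercept` over paired
#' biovolume (µL/mL) and cell dry weight (g/L) measurements. The intercept is
#' estimated (not forced through the origin) so users can check that it is
#' close to zero. Converted CDW values are assigned a 5 % relative standard
#' deviation by default.
#'
#' @param data Data frame with columns `bv` (µL/mL) and `cdw` (g/L); >= 3 rows.
#' @param rel_sd_cdw Relative sd assigned to converted CDW values.
#'
#' @return Object of class `bv_cdw_calibration` with elements `slope`,
#'   `intercept`, `rel_sd_cdw` and the underlying `lm` fit.
#' @export
fit_bv_cdw <- function(data, rel_sd_cdw = 0.05) {
  stopifnot(is.data.frame(data), all(c("bv", "cdw") %in% names(data)))
  if (nrow(data) < 3) {
    stop("need at least 3 paired bv/cdw points", call. = FALSE)
  }
  if (stats::var(data$bv) == 0) {
    stop("bv values have zero variance; slope not identifiable",
         call. = FALSE)
  }
  fit <- stats::lm(cdw ~ bv, data = data)
  co <- stats::coef(fit)
  structure(
    list(slope = unname(co["bv"]), intercept = unname(co["(Intercept)"]),
         rel_sd_cdw = rel_sd_cdw, fit = fit, n = nrow(data)),
    class = "bv_cdw_calibration"
  )
}

#' @export
print.bv_cdw_calibration <- function(x, ...) {
  cat(sprintf(
    "<bv_cdw_calibration> cdw = %.4g * bv + %.4g  (n = %d, rel sd cdw = %g)\n",
    x$slope, x$intercept, x$n, x$rel_sd_cdw))
  invisible(x)
}

#' @rdname fit_bv_cdw
#' @param x A `bv_cdw_calibration`.
#' @param ... Unused.
#' @export
tidy.bv_cdw_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = unname(summary(x$fit)$coefficients[c("bv", "(Intercept)"),
                                                   "Std. Error"]),
    unit = c("gCDW L^-1 per µL mL^-1", "g/L")
  )
}

#' Convert a biovolume series to cell dry weight (and back)
#'
#' Maps a `biomass_bv` measurement series through a fitted calibration line;
#' converted values carry the calibration's assumed relative sd (5 % by
#' default). `cdw_to_bv()` applies the exact inverse map.
#'
#' @param cal A `bv_cdw_calibration`.
#' @param series `measurement_series` tagged `biomass_bv` (or `biomass_cdw`
#'   for the inverse).
#' @return A `measurement_series` with the converted tag.
#' @export
bv_to_cdw <- function(cal, series) {
  stopifnot(inherits(cal, "bv_cdw_calibration"),
            identical(attr(series, "quantity"), "biomass_bv"))
  value <- cal$slope * series$value + cal$intercept
  if (any(value < 0)) {
    stop("calibration maps a biovolume value to negative CDW", call. = FALSE)
  }
  measurement_series(
    tibble::tibble(time_h = series$time_h, value = value,
                   sd = cal$rel_sd_cdw * value),
    "biomass_cdw")
}

#' @rdname bv_to_cdw
#' @export
cdw_to_bv <- function(cal, series) {
  stopifnot(inherits(cal, "bv_cdw_calibration"),
            identical(attr(series, "quantity"), "biomass_cdw"),
            cal$slope > 0)
  value <- (series$value - cal$intercept) / cal$slope
  if (any(value < 0)) {
    stop("calibration maps a CDW value to negative biovolume", call. = FALSE)
  }
  measurement_series(
    tibble::tibble(time_h = series$time_h, value = value,
                   sd = cal$rel_sd_cdw * value),
    "biomass_bv")
}
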