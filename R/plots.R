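# ggplot2 figures for the fitted models, the off-gas balance, the bootstrap
# sample and the carbon-sink decomposition.

#' Plot a rate fit against its data
#'
#' Observed biomass and glucose points (with +/- 1 sd error bars) inside the
#' fitting window, overlaid with the fitted exponential-growth and
#' glucose-depletion curves.
#'
#' @param object A `rate_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_fit <- function(object, ...) {
  b <- object$data$biomass
  g <- object$data$glucose
  obs <- dplyr::bind_rows(
    tibble::tibble(time_h = b$time_h, value = b$value, sd = b$sd,
                   series = paste0("biomass [", object$biomass_unit, "]")),
    tibble::tibble(time_h = g$time_h, value = g$value, sd = g$sd,
                   series = "glucose [mmol/L]")
  )
  tt <- seq(object$window$t_start, object$window$t_end, length.out = 100)
  curves <- dplyr::bind_rows(
    tibble::tibble(time_h = tt,
                   value = model_biomass(object$x0, object$mu, tt),
                   series = paste0("biomass [", object$biomass_unit, "]")),
    tibble::tibble(time_h = tt,
                   value = model_glucose(object$c_const, object$pi_glc,
                                         object$mu, object$x0, tt),
                   series = "glucose [mmol/L]")
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      width = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "#2166ac") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time since inoculation [h]", y = NULL,
                  title = sprintf("mu = %.3g 1/h, pi_GLC = %.3g",
                                  object$mu, object$pi_glc)) +
    ggplot2::theme_bw()
}

#' Plot the off-gas CO2 balance
#'
#' Biomass-specific CO2 formation rate over time; points inside the
#' exponential-phase window are highlighted and the window mean drawn as a
#' horizontal line.
#'
#' @param object A `gas_balance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gas_balance <- function(object, ...) {
  s <- object$series
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_h,
                                  y = .data$pi_co2_specific,
                                  colour = .data$in_window)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$pi_co2_mean,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey60"),
                                 name = "in window") +
    ggplot2::labs(x = "time since inoculation [h]",
                  y = paste0("specific CO2 rate [", object$unit, "]")) +
    ggplot2::theme_bw()
}

#' Plot a bootstrap parameter sample
#'
#' Histograms of the bootstrap sample per parameter with the point estimate
#' (solid) and percentile bounds (dashed) marked.
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples, dplyr::everything(),
                              names_to = "term", values_to = "value")
  marks <- tidy(object)[c("term", "estimate", "lower", "upper")]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$estimate)) +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$lower),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$upper),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "bootstrap refits",
                  title = sprintf("%d samples, alpha = %g",
                                  object$n_samples - object$n_failed,
                                  object$alpha)) +
    ggplot2::theme_bw()
}

#' Stacked carbon-sink bars for one or more strains
#'
#' Carbon equivalents of growth (biomass sink) and CO2 formation stacked per
#' strain, relative to the carbon-uptake rate; the headroom to 1 is the
#' unaccounted gap. Accepts a named list of `carbon_balance` objects.
#'
#' @param balances Named list of `carbon_balance` objects (names are strain
#'   labels).
#' @return A ggplot.
#' @export
plot_carbon_sinks <- function(balances) {
  stopifnot(length(balances) > 0)
  if (is.null(names(balances))) {
    names(balances) <- paste0("strain_", seq_along(balances))
  }
  df <- purrr::imap_dfr(balances, function(cb, nm) {
    s <- sink_decomposition(cb)
    tibble::tibble(strain = nm,
                   sink = factor(c("biomass", "CO2"),
                                 levels = c("CO2", "biomass")),
                   fraction = c(s[["biomass_fraction"]], s[["co2_fraction"]]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$fraction,
                                   fill = .data$sink)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(biomass = "#2166ac",
                                          CO2 = "grey60")) +
    ggplot2::labs(x = NULL, y = "fraction of carbon uptake rate") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.carbon_balance <- function(object, ...) {
  plot_carbon_sinks(list(balance = object))
}
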