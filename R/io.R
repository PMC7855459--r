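# File formats, run configuration and the end-to-end pipeline.
# CSV dialect: comma-separated, UTF-8, dot decimal, header row required.

#' Read a measurement time series from CSV
#'
#' Expects columns `time_h` and `value`; an `sd` column is optional and, when
#' absent, per-point sds are filled as `default_rel_sd * value`. Rows with a
#' blank value are dropped (with a message giving the count).
#'
#' @param path CSV file path.
#' @param quantity Quantity tag, see [measurement_series()].
#' @param default_rel_sd Relative sd used when the file has no `sd` column
#'   (default 0.05, the assumed relative error of derived CDW).
#' @return A `measurement_series`.
#' @export
read_timeseries_csv <- function(path, quantity, default_rel_sd = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  if (nrow(df) == 0) stop("empty time-series file: ", path, call. = FALSE)
  if (!all(c("time_h", "value") %in% names(df))) {
    stop("expected columns time_h and value in ", path, call. = FALSE)
  }
  if (anyNA(df$time_h)) {
    stop("unparseable or missing times in ", path, call. = FALSE)
  }
  n_blank <- sum(is.na(df$value))
  if (n_blank > 0) {
    message("dropping ", n_blank, " row(s) with blank value from ", path)
    df <- df[!is.na(df$value), , drop = FALSE]
  }
  dup <- which(diff(df$time_h) <= 0)
  if (length(dup) > 0) {
    stop("times not strictly increasing in ", path, " at row ", dup[1] + 1,
         call. = FALSE)
  }
  if ("sd" %in% names(df)) {
    measurement_series(df, quantity)
  } else {
    measurement_series(df, quantity, rel_sd = default_rel_sd)
  }
}

#' Write a measurement time series to CSV
#'
#' @param series A `measurement_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series)[c("time_h", "value", "sd")],
                   path)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects everything one pipeline run needs: dataset file paths, gas and
#' reactor conditions, carbon parameters, bootstrap settings and optional
#' window overrides. All defaults are recorded in the run log so every
#' configurable constant actually used is auditable.
#'
#' @param biomass_csv,glucose_csv,offgas_o2_csv,offgas_co2_csv Time-series
#'   file paths (see [read_timeseries_csv()]).
#' @param biomass_quantity `"biomass_cdw"` or `"biomass_bv"`.
#' @param gas [gas_conditions()].
#' @param reactor_volume Working volume, L.
#' @param carbon [carbon_params()].
#' @param n_boot,alpha,seed Bootstrap settings (see [bootstrap_fit()]).
#' @param t_start,t_end Optional window overrides; when both are given,
#'   CO2-peak detection is bypassed.
#' @param default_rel_sd Relative sd for series files without an `sd` column.
#' @param strain Strain label.
#' @param output_dir Directory for the results table and run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(biomass_csv, glucose_csv, offgas_o2_csv,
                       offgas_co2_csv, biomass_quantity = "biomass_cdw",
                       gas = gas_conditions(), reactor_volume = 1,
                       carbon = carbon_params(), n_boot = 1000,
                       alpha = 0.25, seed = 1L,
                       t_start = NULL, t_end = NULL,
                       default_rel_sd = 0.05, strain = "unnamed",
                       output_dir = NULL) {
  structure(
    list(biomass_csv = biomass_csv, glucose_csv = glucose_csv,
         offgas_o2_csv = offgas_o2_csv, offgas_co2_csv = offgas_co2_csv,
         biomass_quantity = match.arg(biomass_quantity,
                                      c("biomass_cdw", "biomass_bv")),
         gas = gas, reactor_volume = reactor_volume, carbon = carbon,
         n_boot = n_boot, alpha = alpha, seed = as.integer(seed),
         t_start = t_start, t_end = t_end,
         default_rel_sd = default_rel_sd, strain = strain,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Nested keys `gas:` and `carbon:` take the argument names of
#' [gas_conditions()] and [carbon_params()]; everything else maps onto
#' [run_config()] arguments. Relative dataset paths are resolved against the
#' YAML file's directory.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  args <- y
  args$gas <- if (is.null(y$gas)) gas_conditions() else
    do.call(gas_conditions, y$gas)
  args$carbon <- if (is.null(y$carbon)) carbon_params() else
    do.call(carbon_params, y$carbon)
  for (k in c("biomass_csv", "glucose_csv", "offgas_o2_csv",
              "offgas_co2_csv")) {
    args[[k]] <- resolve(y[[k]])
  }
  do.call(run_config, args)
}

#' Run the end-to-end analysis pipeline for one reactor
#'
#' Reads the four time series, validates the dataset, detects (or takes) the
#' exponential-phase window, fits the growth/uptake model, bootstraps its
#' uncertainty, balances the off-gas CO2, and computes the instantaneous
#' carbon balance with propagated error. When `output_dir` is set, a tidy
#' results table (`<strain>_results.csv`: parameter, estimate, lower, upper,
#' unit) and a run log recording every configurable constant used are
#' written; outputs are removed again if any later stage fails.
#'
#' Standard errors entering the carbon balance are the bootstrap-sample
#' standard deviations of `mu` and `pi_glc` and the analytically propagated
#' analyzer error of the mean CO2 rate.
#'
#' @param cfg A [run_config()] or path to a YAML config.
#' @return A list of class `pipeline_result` with the dataset, window, fit,
#'   bootstrap, gas balance, carbon balance and the tidy `results` table.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  for (k in c("biomass_csv", "glucose_csv", "offgas_o2_csv",
              "offgas_co2_csv")) {
    if (!file.exists(cfg[[k]])) {
      stop("missing input file (", k, "): ", cfg[[k]], call. = FALSE)
    }
  }
  ds <- batch_dataset(
    biomass = read_timeseries_csv(cfg$biomass_csv, cfg$biomass_quantity,
                                  cfg$default_rel_sd),
    glucose = read_timeseries_csv(cfg$glucose_csv, "glucose",
                                  cfg$default_rel_sd),
    offgas_o2 = read_timeseries_csv(cfg$offgas_o2_csv, "o2_out",
                                    cfg$default_rel_sd),
    offgas_co2 = read_timeseries_csv(cfg$offgas_co2_csv, "co2_out",
                                     cfg$default_rel_sd),
    gas = cfg$gas, reactor_volume = cfg$reactor_volume, strain = cfg$strain
  )

  window <- if (!is.null(cfg$t_start) && !is.null(cfg$t_end)) {
    phase_window(cfg$t_start, cfg$t_end)
  } else {
    detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
  }
  fit <- fit_rates(ds, window)
  boot <- bootstrap_fit(ds, window, n = cfg$n_boot, alpha = cfg$alpha,
                        seed = cfg$seed, fit = fit)
  gb <- offgas_balance(ds, fit, window)
  bt <- tidy(boot)
  cb <- carbon_balance(
    mu = fit$mu, pi_glc = fit$pi_glc, pi_co2 = gb$pi_co2_mean,
    sd_mu = bt$sd[bt$term == "mu"],
    sd_pi_glc = bt$sd[bt$term == "pi_glc"],
    sd_pi_co2 = ifelse(is.na(gb$sd_pi_co2_mean), 0, gb$sd_pi_co2_mean),
    cp = cfg$carbon
  )

  results <- dplyr::bind_rows(
    bt[c("term", "estimate", "lower", "upper", "unit")],
    tibble::tibble(term = "pi_co2", estimate = gb$pi_co2_mean,
                   lower = NA_real_, upper = NA_real_, unit = gb$unit),
    tibble::tibble(term = "theta", estimate = cb$theta,
                   lower = cb$theta - cb$sd_theta,
                   upper = cb$theta + cb$sd_theta, unit = "-")
  )
  names(results)[1] <- "parameter"
  for (col in c("estimate", "lower", "upper")) {
    results[[col]] <- unname(results[[col]])
  }

  out <- structure(
    list(dataset = ds, window = window, fit = fit, bootstrap = boot,
         gas_balance = gb, carbon_balance = cb, results = results,
         config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(cfg$output_dir)) {
    write_pipeline_outputs(out, cfg)
  }
  out
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  slug <- gsub("[^A-Za-z0-9._-]+", "_", cfg$strain)
  results_path <- file.path(cfg$output_dir, paste0(slug, "_results.csv"))
  log_path <- file.path(cfg$output_dir, paste0(slug, "_run.log"))
  tryCatch({
    readr::write_csv(res$results, results_path)
    writeLines(run_log_lines(res, cfg), log_path)
  }, error = function(e) {
    unlink(c(results_path, log_path))
    stop(e)
  })
  invisible(res)
}

run_log_lines <- function(res, cfg) {
  g <- cfg$gas; cp <- cfg$carbon
  c(sprintf("strain: %s", cfg$strain),
    sprintf("reactor_volume_L: %g", cfg$reactor_volume),
    sprintf("gas_flow_m3_h: %g", g$flow_m3_h),
    sprintf("pressure_pa: %g", g$pressure_pa),
    sprintf("temperature_k: %g", g$temperature_k),
    sprintf("gas_constant: %g", g$gas_constant),
    sprintf("phi_o2_in_volpct: %g", g$phi_o2_in),
    sprintf("phi_co2_in_volpct: %g", g$phi_co2_in),
    sprintf("omega_c: %g", cp$omega_c),
    sprintf("sd_omega_c: %g", cp$sd_omega_c),
    sprintf("m_c_g_per_mmol: %g", cp$m_c),
    sprintf("n_boot: %d", cfg$n_boot),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("seed: %d", cfg$seed),
    sprintf("default_rel_sd: %g", cfg$default_rel_sd),
    sprintf("window_t_start_h: %g", res$window$t_start),
    sprintf("window_t_end_h: %g", res$window$t_end),
    sprintf("window_source: %s",
            if (is.null(cfg$t_start)) "co2_peak_detection" else "override"),
    sprintf("theta: %.6g", res$carbon_balance$theta),
    sprintf("sd_theta: %.6g", res$carbon_balance$sd_theta))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> strain:", x$dataset$strain, "\n")
  print(x$results)
  invisible(x)
}

#' Envelope summary over replicate cultivations
#'
#' Combines per-reactor results tables of replicate cultivations of one
#' strain into a single table per parameter: the mean point estimate, the
#' minimum of the lower bounds and the maximum of the upper bounds over all
#' replicates (the conservative replicate-envelope rule).
#'
#' @param results List of tidy results tibbles (column layout of
#'   `pipeline_result$results`) or paths to `*_results.csv` files.
#' @return Tibble with one row per parameter: `parameter`, `estimate`
#'   (replicate mean), `lower` (min over replicates), `upper` (max over
#'   replicates), `unit`, `n_replicates`.
#' @export
summarize_replicates <- function(results) {
  tabs <- purrr::map(results, function(r) {
    if (is.character(r)) readr::read_csv(r, show_col_types = FALSE) else r
  })
  dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$parameter, .data$unit) |>
    dplyr::summarise(
      estimate = mean(.data$estimate),
      lower = if (all(is.na(.data$lower))) NA_real_ else
        min(.data$lower, na.rm = TRUE),
      upper = if (all(is.na(.data$upper))) NA_real_ else
        max(.data$upper, na.rm = TRUE),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("parameter", "estimate", "lower", "upper", "unit",
                  "n_replicates")
}
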