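# Parametric Monte-Carlo bootstrap of the joint rate fit: every in-window
# measurement is perturbed within its own normal distribution via a
# Latin-hypercube sample and the weighted fit is re-performed.

#' Latin-hypercube normal perturbation matrix
#'
#' Per dimension, the unit interval is split into `n` equal-probability
#' strata, one uniform draw is taken in each stratum, the strata order is
#' permuted independently per dimension, and the draws are mapped through the
#' normal inverse CDF with that dimension's mean and sd. Exactly one sample
#' therefore falls in each n-quantile bin of every marginal. Deterministic
#' given `seed`.
#'
#' @param means,sds Numeric vectors of equal length (sds > 0).
#' @param n Number of samples (rows), >= 2.
#' @param seed Integer seed.
#' @return `n x length(means)` matrix of perturbed values.
#' @export
lhs_normal_perturb <- function(means, sds, n, seed) {
  stopifnot(length(means) == length(sds), all(sds > 0), n >= 2)
  u <- withr::with_seed(as.integer(seed),
                        lhs::randomLHS(n, length(means)))
  z <- stats::qnorm(u)
  sweep(sweep(z, 2, sds, "*"), 2, means, "+")
}

#' Bootstrap the joint rate fit
#'
#' Parametric Monte-Carlo bootstrap: for each of `n` Latin-hypercube rows,
#' every biomass and glucose measurement inside the window is replaced by a
#' draw from the normal distribution defined by its value and standard
#' deviation, and the variance-weighted fit is re-performed, warm-started at
#' the point estimate. Off-gas measurements are not perturbed here; gas
#' analyzer uncertainty is propagated analytically in the gas balance
#' instead. Confidence bounds are the `alpha`-th and `(1 - alpha)`-th
#' percentiles of each parameter's sample (linear interpolation between
#' closest ranks); the default `alpha = 0.25` makes the interval the
#' interquartile range. Refits that fail to converge are dropped and counted;
#' more than 10 % failures is an error because silent dropping biases the
#' intervals.
#'
#' @param ds A [batch_dataset()].
#' @param window A [phase_window()].
#' @param n Number of bootstrap samples (default 1000).
#' @param alpha Percentile level of the bounds (default 0.25, the IQR).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param fit Optional pre-computed point fit for `ds`/`window`.
#'
#' @return Object of class `bootstrap_result`: the parameter `samples`
#'   tibble (one row per successful refit), per-parameter `lower`/`upper`
#'   bounds, the point `fit`, `alpha`, `n_samples` and `n_failed`.
#' @export
#' @examples
#' ds <- simulate_batch(strain_preset(), noise_model(seed = 11),
#'                      n_points = 30, dt = 0.6)
#' w <- detect_window(ds$offgas_co2, ds$biomass, glucose = ds$glucose)
#' bootstrap_fit(ds, w, n = 50, seed = 42)
bootstrap_fit <- function(ds, window, n = 1000, alpha = 0.25, seed = 1L,
                          fit = NULL) {
  stopifnot(n >= 2, alpha > 0, alpha < 0.5)
  if (is.null(fit)) fit <- fit_rates(ds, window)
  in_win <- function(s) {
    s[s$time_h >= window$t_start & s$time_h <= window$t_end, , drop = FALSE]
  }
  b <- in_win(ds$biomass)
  g <- in_win(ds$glucose)
  n_b <- nrow(b)
  means <- c(b$value, g$value)
  sds <- c(b$sd, g$sd)
  draws <- lhs_normal_perturb(means, sds, n, seed)

  warm <- c(x0 = fit$x0, mu = fit$mu, pi_glc = fit$pi_glc,
            c_const = fit$c_const)
  one_refit <- function(row) {
    bi <- b; gi <- g
    bi$value <- row[seq_len(n_b)]
    gi$value <- row[-seq_len(n_b)]
    lm_fit <- minpack.lm::nls.lm(
      par = warm, fn = rate_residuals, b = bi, g = gi,
      lower = c(1e-12, 1e-12, 0, -Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-12, ptol = 1e-10, gtol = 0))
    if (!lm_fit$info %in% 1:4) return(NULL)
    lm_fit$par
  }
  results <- purrr::map(seq_len(n), function(i) one_refit(draws[i, ]))
  ok <- !vapply(results, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * n) {
    stop(n_failed, " of ", n, " bootstrap refits failed to converge (> 10 %)",
         call. = FALSE)
  }
  samples <- tibble::as_tibble(do.call(rbind, results[ok]))
  names(samples) <- c("x0", "mu", "pi_glc", "c_const")

  qs <- vapply(samples, stats::quantile,
               probs = c(alpha, 1 - alpha), names = FALSE,
               FUN.VALUE = numeric(2))
  structure(
    list(samples = samples,
         lower = qs[1, ], upper = qs[2, ],
         fit = fit, alpha = alpha, n_samples = n, n_failed = n_failed,
         seed = as.integer(seed)),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> %d samples (%d failed), alpha = %g\n",
    x$n_samples, x$n_failed, x$alpha))
  print(tidy(x))
  invisible(x)
}

#' Tidy a bootstrap result
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return One row per parameter: point estimate, `lower`/`upper` percentile
#'   bounds, bootstrap-sample standard deviation and unit.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  pt <- tidy(x$fit)
  tibble::tibble(
    term = pt$term,
    estimate = pt$estimate,
    lower = unname(x$lower[pt$term]),
    upper = unname(x$upper[pt$term]),
    sd = vapply(x$samples[pt$term], stats::sd, numeric(1)),
    unit = pt$unit
  )
}

#' @rdname tidy.bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_failed = x$n_failed,
                 alpha = x$alpha, seed = x$seed)
}
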