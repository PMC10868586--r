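#' Fit a thermal death time curve to dynamic ramping trials
#'
#' Estimates the heat-sensitivity coefficient `z` and the static thermal
#' limit `t_static` from per-trial mean knockdown temperatures recorded at
#' different heating rates. The fit minimises the sum of squared residuals
#' between each trial's mean knockdown temperature and the ramp prediction
#' [dynamic_knockdown()] at that trial's heating rate and start temperature.
#'
#' Trials, not individual fish, are the unit of fitting: replicate fish
#' within a ramp share one heating rate and contribute a single mean. `z` is
#' identified by the spread of heating rates across trials, so at least two
#' distinct rates are required, and fits from a rate spread narrower than
#' 0.05 degC/min are flagged as ill-conditioned and should be interpreted
#' with care.
#'
#' Optimisation is a deterministic direct search: Nelder-Mead on
#' `(log z, t_static)` restarted from `z` in {3, 5, 7} (and, for each, from
#' the best point found), with the start value of `t_static` taken from the
#' data. No randomness is involved, so fits are reproducible without seeds.
#'
#' @param trials A data frame with one row per trial and numeric columns
#'   `heating_rate` (degC/min), `start_temp` (degC) and `mean_knockdown`
#'   (degC). The column names used by [read_trials()]
#'   (`heating_rate_c_per_min`, `start_temp_c`, `mean_knockdown_c`) are also
#'   accepted. Optional columns (`trial_id`, `species`, `oxygen`, `n_fish`)
#'   are carried into the diagnostics.
#' @param t_ref Reference duration in minutes anchoring `t_static`
#'   (default 1).
#' @return An object of class `tdt_fit`: a list with elements
#'   `params` ([tdt_params()]), `data` (the trial tibble with `fitted` and
#'   `residual` columns), `rss`, `n_trials`, `rate_spread`, `convergence`
#'   and `warnings` (character vector of fit caveats). Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @examples
#' p <- tdt_params(z = 4.19, t_static = 38)
#' trials <- data.frame(
#'   heating_rate = c(0.2, 0.4, 0.5), start_temp = 26,
#'   mean_knockdown = dynamic_knockdown(p, 26, c(0.2, 0.4, 0.5))
#' )
#' fit <- fit_tdt(trials)
#' tidy(fit)
#' @export
fit_tdt <- function(trials, t_ref = 1) {
  trials <- normalise_trials(trials)
  if (nrow(trials) < 2L) {
    abort("At least two trials are needed to fit a TDT curve.",
      class = "thermotol_error_unidentifiable"
    )
  }
  rate_spread <- diff(range(trials$heating_rate))
  if (rate_spread == 0) {
    abort("z unidentifiable from a single rate: all trials share one heating rate.",
      class = "thermotol_error_unidentifiable"
    )
  }

  obs <- trials$mean_knockdown
  rate <- trials$heating_rate
  start <- trials$start_temp

  rss_of <- function(theta) {
    z <- exp(theta[1L])
    ts <- theta[2L]
    pred <- ts + z * log10(rate * log(10) * t_ref / z + 10^((start - ts) / z))
    sum((obs - pred)^2)
  }

  ts0 <- max(obs)
  best <- NULL
  for (z0 in c(3, 5, 7)) {
    fit <- optim(c(log(z0), ts0 + 4), rss_of,
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best point found (Nelder-Mead can stall near the optimum)
  for (i in 1:2) {
    best2 <- optim(best$par, rss_of,
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14)
    )
    if (best2$value <= best$value) best <- best2
  }

  z_hat <- exp(best$par[1L])
  ts_hat <- best$par[2L]

  fit_warnings <- character()
  if (rate_spread < 0.05) {
    fit_warnings <- c(fit_warnings, sprintf(
      "heating-rate spread %.3f degC/min is below 0.05: z is ill-conditioned; interpret with care",
      rate_spread
    ))
  }
  if (z_hat > 20) {
    fit_warnings <- c(fit_warnings, sprintf(
      "fitted z = %.3g is suspiciously large (nearly rate-insensitive curve)", z_hat
    ))
  }
  params <- withCallingHandlers(
    tdt_params(z = z_hat, t_static = ts_hat, t_ref = t_ref),
    warning = function(w) {
      fit_warnings <<- c(fit_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  fitted_vals <- dynamic_knockdown(params, start, rate)
  out <- structure(
    list(
      params = params,
      data = dplyr::mutate(trials,
        fitted = fitted_vals,
        residual = obs - fitted_vals
      ),
      rss = best$value,
      n_trials = nrow(trials),
      rate_spread = rate_spread,
      convergence = best$convergence,
      warnings = fit_warnings
    ),
    class = "tdt_fit"
  )
  for (w in fit_warnings) warn(w)
  out
}

normalise_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  aliases <- c(
    heating_rate = "heating_rate_c_per_min",
    start_temp = "start_temp_c",
    mean_knockdown = "mean_knockdown_c"
  )
  for (nm in names(aliases)) {
    if (!nm %in% names(trials) && aliases[[nm]] %in% names(trials)) {
      trials[[nm]] <- trials[[aliases[[nm]]]]
    }
  }
  required <- c("heating_rate", "start_temp", "mean_knockdown")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0L) {
    abort(
      sprintf("Trial data is missing required column(s): %s.", toString(missing)),
      class = "thermotol_error_missing_column",
      column = missing
    )
  }
  if (any(trials$heating_rate <= 0)) {
    abort("All trial heating rates must be > 0.", class = "thermotol_error_rate")
  }
  if (any(trials$mean_knockdown <= trials$start_temp)) {
    abort("Each trial's mean knockdown temperature must exceed its start temperature.",
      class = "thermotol_error_trials"
    )
  }
  trials
}

#' @export
print.tdt_fit <- function(x, ...) {
  cat("<tdt_fit>\n")
  cat(sprintf(
    "  z = %.4g degC/log10(min), t_static = %.4g degC (t_ref = %.3g min)\n",
    x$params$z, x$params$t_static, x$params$t_ref
  ))
  cat(sprintf("  trials: %d, RSS: %.4g, rate spread: %.3f degC/min\n",
    x$n_trials, x$rss, x$rate_spread))
  if (length(x$warnings) > 0) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' @rdname fit_tdt
#' @param x A `tdt_fit` object.
#' @param ... Unused.
#' @method tidy tdt_fit
#' @export
tidy.tdt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("z", "t_static"),
    estimate = c(x$params$z, x$params$t_static)
  )
}

#' @rdname fit_tdt
#' @method glance tdt_fit
#' @export
glance.tdt_fit <- function(x, ...) {
  tibble::tibble(
    z = x$params$z,
    t_static = x$params$t_static,
    t_ref = x$params$t_ref,
    rss = x$rss,
    n_trials = x$n_trials,
    rate_spread = x$rate_spread,
    convergence = x$convergence,
    n_warnings = length(x$warnings)
  )
}
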