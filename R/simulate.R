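#' Simulate individual CTmax assay records
#'
#' Generates fish-level knockdown records from the TDT model run "forwards":
#' each fish draws an individual static limit
#' `t_static_i ~ Normal(t_static, between_fish_sd)` (one-parameter
#' individual heterogeneity - the spread of individual CTmax values is well
#' documented, individual variation in `z` is not), and its knockdown
#' temperature is the closed-form ramp solution [dynamic_knockdown()] at its
#' trial's heating rate. Per-trial heating rates are jittered around the
#' target rate with sd `rate_sd` and truncated below at 0.05 degC/min,
#' mimicking the run-to-run variability of a heated test tank.
#'
#' Defaults emulate a hypoxic-treatment CTmax experiment in the warm season:
#' ramps of ~0.42 +/- 0.06 degC/min starting at the 30 degC holding
#' temperature, with around 16 fish per trial.
#'
#' @param n_trials Number of ramping trials (default 3).
#' @param n_fish Fish per trial (default 16).
#' @param z,t_static,t_ref Generating TDT parameters; see [tdt_params()].
#' @param between_fish_sd Standard deviation of individual static limits,
#'   degC (default 0.5).
#' @param heating_rate Target ramp rate, degC/min (default 0.42).
#' @param rate_sd Between-trial sd of the realised ramp rate (default 0.06).
#' @param start_temp Ramp start / holding temperature, degC (default 30).
#' @param species,oxygen Labels carried into the records.
#' @param seed Optional integer seed; the output is deterministic under it.
#' @return A tibble of assay records: `fish_id`, `species`, `oxygen`,
#'   `trial_id`, `direction` (`"heat"`), `heating_rate` (the trial's
#'   realised rate), `start_temp`, `knockdown_temp_c`,
#'   `standard_length_mm`, `collection_temp_c`.
#' @export
simulate_assay <- function(n_trials = 3, n_fish = 16,
                           z = 5.58, t_static = 45.6, t_ref = 1,
                           between_fish_sd = 0.5,
                           heating_rate = 0.42, rate_sd = 0.06,
                           start_temp = 30,
                           species = "P. sulphuraria", oxygen = "hypoxic",
                           seed = NULL) {
  stopifnot(between_fish_sd >= 0, heating_rate > 0, rate_sd >= 0, n_trials >= 1, n_fish >= 1)
  gen <- function() {
    params0 <- suppressWarnings(tdt_params(z, t_static, t_ref))
    purrr::map_dfr(seq_len(n_trials), function(tr) {
      rate <- rtrunc_normal(1, heating_rate, rate_sd, lower = 0.05)
      ts_i <- rnorm(n_fish, t_static, between_fish_sd)
      kd <- vapply(ts_i, function(tsi) {
        dynamic_knockdown(
          suppressWarnings(tdt_params(z, tsi, t_ref)),
          start_temp, rate
        )
      }, numeric(1))
      tibble::tibble(
        fish_id = sprintf("%s_t%d_f%02d", gsub("[^A-Za-z]", "", species), tr, seq_len(n_fish)),
        species = species,
        oxygen = oxygen,
        trial_id = sprintf("%s_%s_trial%d", gsub("[^A-Za-z]", "", species), oxygen, tr),
        direction = "heat",
        heating_rate = rate,
        start_temp = start_temp,
        knockdown_temp_c = kd,
        standard_length_mm = round(pmax(rnorm(n_fish, 20, 2.5), 12), 1),
        collection_temp_c = start_temp
      )
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

rtrunc_normal <- function(n, mean, sd, lower) {
  if (sd == 0) {
    return(rep(max(mean, lower), n))
  }
  out <- rnorm(n, mean, sd)
  while (any(out < lower)) {
    bad <- out < lower
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  out
}

#' Aggregate assay records into per-trial summaries
#'
#' Collapses fish-level records to the unit at which TDT curves are fitted:
#' one mean knockdown temperature per trial with its realised heating rate.
#'
#' @param records Assay records as produced by [simulate_assay()] or read
#'   with [read_assays()]; needs columns `trial_id`, `species`, `oxygen`,
#'   `heating_rate`, `start_temp`, `knockdown_temp_c`.
#' @return A tibble with `trial_id`, `species`, `oxygen`, `heating_rate`,
#'   `start_temp`, `mean_knockdown`, `n_fish`.
#' @export
trial_summaries <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("trial_id", "species", "oxygen", "heating_rate", "start_temp", "knockdown_temp_c")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    abort(
      sprintf("Assay records are missing required column(s): %s.", toString(missing)),
      class = "thermotol_error_missing_column", column = missing
    )
  }
  records |>
    dplyr::group_by(.data$trial_id, .data$species, .data$oxygen) |>
    dplyr::summarise(
      heating_rate = .data$heating_rate[1L],
      start_temp = .data$start_temp[1L],
      mean_knockdown = mean(.data$knockdown_temp_c),
      n_fish = dplyr::n(),
      .groups = "drop"
    )
}

#' Simulate a diel temperature-logger series
#'
#' Emulates an hourly water-temperature logger in a geothermally heated
#' stream: a single-harmonic diel cycle
#' `daily_mean + diel_amplitude * cos(2 * pi * (t - time_of_max) / 24 h)`
#' plus Gaussian observation noise, optionally with a transient heat spike
#' (a constant excess over a start/duration window) injected on one day.
#'
#' Defaults reproduce a warm-season pool profile with daily range
#' 28.2-35.2 degC (mean 31.7, amplitude 3.5) peaking mid-afternoon.
#'
#' @param n_days Number of days (default 14).
#' @param daily_mean Mean temperature, degC (default 31.7).
#' @param diel_amplitude Half-range of the diel cycle, degC (default 3.5).
#' @param time_of_max Clock hour of the daily maximum (default 15).
#' @param obs_noise_sd Observation noise sd, degC (default 0).
#' @param sampling_interval Minutes between readings (default 60).
#' @param site_id Site label (default `"site_2"`).
#' @param start_date First day (default `"2023-05-08"`).
#' @param spike Optional `list(day =, start_hour =, excess =, duration_min =)`
#'   describing a transient heat event.
#' @param seed Optional integer seed.
#' @return A logger tibble (`site_id`, `timestamp`, `temp_c`) accepted by
#'   all `field_thermal` functions.
#' @export
simulate_logger <- function(n_days = 14, daily_mean = 31.7, diel_amplitude = 3.5,
                            time_of_max = 15, obs_noise_sd = 0,
                            sampling_interval = 60, site_id = "site_2",
                            start_date = "2023-05-08", spike = NULL,
                            seed = NULL) {
  stopifnot(diel_amplitude >= 0, sampling_interval > 0, n_days >= 1, obs_noise_sd >= 0)
  gen <- function() {
    t0 <- lubridate::as_datetime(paste(start_date, "00:00:00"), tz = "UTC")
    minutes <- seq(0, n_days * 1440 - sampling_interval, by = sampling_interval)
    hours <- minutes / 60
    temp <- daily_mean + diel_amplitude * cos(2 * pi * ((hours %% 24) - time_of_max) / 24)
    if (obs_noise_sd > 0) temp <- temp + rnorm(length(temp), 0, obs_noise_sd)
    if (!is.null(spike)) {
      onset_min <- (spike$day - 1) * 1440 + spike$start_hour * 60
      in_spike <- minutes >= onset_min & minutes < onset_min + spike$duration_min
      temp[in_spike] <- temp[in_spike] + spike$excess
    }
    tibble::tibble(
      site_id = site_id,
      timestamp = t0 + lubridate::dminutes(minutes),
      temp_c = temp
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Choose a static limit reproducing a target dynamic CTmax
#'
#' Inverts [dynamic_knockdown()] in `t_static`: given `z` and ramp
#' conditions, finds the static limit for which the ramp knockdown equals a
#' target mean CTmax. Useful for building generator configurations around
#' published dynamic CTmax values, since the static limit itself is rarely
#' printed.
#'
#' @param z Heat-sensitivity coefficient.
#' @param target_ctmax Desired ramp knockdown temperature, degC.
#' @param start_temp,heating_rate Ramp conditions.
#' @param t_ref Reference duration, minutes.
#' @return The `t_static` value (degC) solving the ramp equation.
#' @export
t_static_for_ctmax <- function(z, target_ctmax, start_temp, heating_rate, t_ref = 1) {
  stopifnot(z > 0, heating_rate > 0, target_ctmax > start_temp)
  f <- function(ts) {
    ts + z * log10(heating_rate * log(10) * t_ref / z + 10^((start_temp - ts) / z)) -
      target_ctmax
  }
  uniroot(f, lower = target_ctmax - 1, upper = target_ctmax + 10 * z, tol = 1e-10)$root
}
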