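# Independent oracles and small fixture builders used across the suite.

# Numeric knockdown oracle: integrate the injury rate over temperature on a
# fine grid (dT = step) and locate the injury = 1 crossing by interpolating
# the cumulative integral. Shares no code with dynamic_knockdown().
numeric_knockdown_oracle <- function(z, t_static, start, rate, t_ref = 1,
                                     step = 1e-3) {
  upper <- t_static + 3 * z
  grid <- seq(start, upper, by = step)
  g <- 10^((grid - t_static) / z) / (rate * t_ref) # injury per degC of ramp
  cum <- cumsum((head(g, -1) + tail(g, -1)) / 2) * step
  i <- which(cum >= 1)[1L]
  if (is.na(i)) stop("oracle grid too short")
  c0 <- if (i == 1L) 0 else cum[i - 1L]
  grid[i] + (1 - c0) / (cum[i] - c0) * step
}

# Linear heating ramp sampled at fixed time resolution, as a trajectory
# data frame for injury_integral().
ramp_trajectory <- function(start_temp, rate, end_temp, by_min = 0.1) {
  end_min <- (end_temp - start_temp) / rate
  tt <- unique(c(seq(0, end_min, by = by_min), end_min))
  data.frame(time_min = tt, temp_c = start_temp + rate * tt)
}

# Hourly logger day(s) built from an arbitrary temperature-of-clock-hour
# function, for field_thermal tests.
hourly_series <- function(f_hour, n_days = 1, site_id = "site_x",
                          start_date = "2023-05-08") {
  t0 <- lubridate::as_datetime(paste(start_date, "00:00:00"), tz = "UTC")
  hours <- seq(0, n_days * 24 - 1)
  tibble::tibble(
    site_id = site_id,
    timestamp = t0 + lubridate::dhours(hours),
    temp_c = f_hour(hours %% 24)
  )
}

# Asymmetric diel cycle: minimum at 06:00, maximum at 15:00, built from two
# half-cosines so the extremes are attained exactly at those clock hours.
asymmetric_diel <- function(h, t_min = 28.2, t_max = 35.2) {
  amp <- (t_max - t_min) / 2
  mid <- (t_max + t_min) / 2
  rising <- h >= 6 & h <= 15
  phase <- ifelse(rising,
    (h - 6) / 9, # 0 at min, 1 at max
    ifelse(h > 15, (h - 15) / 15, (h + 9) / 15) # fall over 15 h
  )
  ifelse(rising,
    mid - amp * cos(pi * phase),
    mid + amp * cos(pi * phase)
  )
}

# Balanced 2x2 fish-level assay records with chosen cell means, for the
# permutation-test checks. Interaction enters on species "B" under hypoxia.
make_2x2_records <- function(n_trials = 3, n_fish = 12, sd_fish = 0.8,
                             base = 41, oxygen_effect = -0.5,
                             species_effect = -0.3, interaction = 0) {
  grid <- expand.grid(
    species = c("A", "B"), oxygen = c("normoxic", "hypoxic"),
    trial = seq_len(n_trials), stringsAsFactors = FALSE
  )
  purrr::pmap_dfr(grid, function(species, oxygen, trial) {
    mu <- base +
      (oxygen == "hypoxic") * oxygen_effect +
      (species == "B") * species_effect +
      (species == "B" && oxygen == "hypoxic") * interaction
    tibble::tibble(
      fish_id = sprintf("%s_%s_%d_%02d", species, oxygen, trial, seq_len(n_fish)),
      species = species,
      oxygen = oxygen,
      trial_id = sprintf("%s_%s_%d", species, oxygen, trial),
      direction = "heat",
      knockdown_temp_c = rnorm(n_fish, mu, sd_fish)
    )
  })
}
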