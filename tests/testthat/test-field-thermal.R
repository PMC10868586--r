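test_that("a constant day summarises to equal extremes and zero heating rate", {
  series <- hourly_series(function(h) rep(30, length(h)))
  out <- daily_summaries(series)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_temp, 30)
  expect_equal(out$min_temp, 30)
  expect_equal(out$max_temp, 30)
  expect_equal(out$heating_rate, 0)
  expect_false(out$partial)
})

test_that("an asymmetric diel day reproduces its constructed extremes", {
  series <- hourly_series(asymmetric_diel, n_days = 3)
  out <- daily_summaries(series)
  expect_equal(out$min_temp, rep(28.2, 3))
  expect_equal(out$max_temp, rep(35.2, 3))
  expect_equal(lubridate::hour(out$time_of_min), rep(6, 3))
  expect_equal(lubridate::hour(out$time_of_max), rep(15, 3))
  # dawn-minimum anchor: (35.2 - 28.2) / 540 min, reported to 3 decimals
  expect_equal(out$heating_rate, rep(0.013, 3))
})

test_that("single-reading days are dropped with a warning and partial days flagged", {
  full_day <- hourly_series(function(h) 29 + 0.1 * h)
  lone <- tibble::tibble(
    site_id = "site_x",
    timestamp = lubridate::as_datetime("2023-05-09 10:00:00", tz = "UTC"),
    temp_c = 31
  )
  expect_warning(out <- daily_summaries(dplyr::bind_rows(full_day, lone)), "single reading")
  expect_equal(nrow(out), 1L)
  short <- full_day[1:10, ] # 10 of 24 expected hourly readings
  expect_true(daily_summaries(short)$partial)
})

test_that("empty input gives an empty summary, not an error", {
  empty <- tibble::tibble(
    site_id = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    temp_c = numeric()
  )
  expect_equal(nrow(daily_summaries(empty)), 0L)
})

test_that("heating rate matches the hand-worked anchor example", {
  # 28.0 degC at the 06:00 dawn minimum, 33.6 degC maximum at 14:00:
  # 5.6 degC over 480 min -> 0.01167, reported as 0.012
  f <- function(h) {
    ifelse(h < 6, 28.5 - h / 12, ifelse(h <= 14, 28 + 5.6 * (h - 6) / 8, 33.6 - (h - 14) / 4))
  }
  out <- heating_rates(hourly_series(f))
  expect_equal(out$heating_rate, 0.012)
  expect_equal(out$anchor_temp, 28.0)
  expect_equal(lubridate::hour(out$anchor_time), 6)
  # fixed-clock policy anchors at 06:00 here too, same answer
  out_fixed <- heating_rates(hourly_series(f), sunrise_policy = "fixed", fixed_time = "06:00")
  expect_equal(out_fixed$heating_rate, 0.012)
})

test_that("a day whose maximum precedes the anchor yields NA with a warning", {
  f <- function(h) 35 - 0.2 * h # monotone cooling from midnight
  expect_warning(out <- heating_rates(hourly_series(f)), "undefined")
  expect_true(is.na(out$heating_rate))
})

test_that("generator days recover their construction heating rate", {
  # cosine diel cycle, amplitude 3.5 rising from the 03:00 minimum to the
  # 15:00 maximum: 7 degC over 720 min = 0.00972 -> 0.010 at 3 decimals
  series <- simulate_logger(n_days = 2)
  out <- heating_rates(series)
  expect_equal(out$heating_rate, rep(round(7 / 720, 3), 2), tolerance = 1e-9)
})

test_that("exposure durations solve band crossings exactly", {
  t0 <- lubridate::as_datetime("2023-05-08 10:00:00", tz = "UTC")
  two <- tibble::tibble(
    site_id = "s",
    timestamp = t0 + lubridate::dminutes(c(0, 60)),
    temp_c = c(31, 33)
  )
  out <- exposure_durations(two, band_edges = c(32, 33))
  expect_equal(out$minutes, 30)
  # all below the bands: zero everywhere
  cold <- dplyr::mutate(two, temp_c = c(29, 31))
  expect_true(all(exposure_durations(cold, band_edges = 32:36)$minutes == 0))
})

test_that("a stepped day yields its constructed minutes in band", {
  # 1-min sampling: hold 34.5 for exactly 120 min inside [34, 35)
  t0 <- lubridate::as_datetime("2023-05-08 00:00:00", tz = "UTC")
  mins <- seq(0, 1439)
  temp <- ifelse(mins >= 600 & mins < 720, 34.5, 30)
  day <- tibble::tibble(site_id = "s", timestamp = t0 + lubridate::dminutes(mins), temp_c = temp)
  out <- exposure_durations(day, band_edges = c(34, 35))
  expect_equal(out$minutes, 120, tolerance = 2)
})

test_that("band minutes are conserved and invariant under segment refinement", {
  series <- simulate_logger(n_days = 3)
  span_min <- as.numeric(difftime(max(series$timestamp), min(series$timestamp), units = "mins"))
  edges <- seq(floor(min(series$temp_c)) - 1, ceiling(max(series$temp_c)) + 1, by = 1)
  out <- exposure_durations(series, band_edges = edges)
  expect_equal(sum(out$minutes), span_min, tolerance = 1e-9)

  # resample each hourly segment at 1-min resolution: linear interpolation
  # makes the band minutes identical
  fine_t <- seq(min(series$timestamp), max(series$timestamp), by = "1 min")
  fine <- tibble::tibble(
    site_id = "site_2",
    timestamp = fine_t,
    temp_c = approx(series$timestamp, series$temp_c, xout = fine_t)$y
  )
  out_fine <- exposure_durations(fine, band_edges = c(32, 33, 34, 35, 36))
  out_coarse <- exposure_durations(series, band_edges = c(32, 33, 34, 35, 36))
  expect_equal(out_fine$minutes, out_coarse$minutes, tolerance = 1e-6)
})

test_that("overlapping or unsorted bands are rejected", {
  series <- simulate_logger(n_days = 2)
  expect_error(exposure_durations(series, band_edges = c(34, 33)), class = "thermotol_error_bands")
  expect_error(exposure_durations(series, band_edges = c(33, 33)), class = "thermotol_error_bands")
})

test_that("an injected one-degree spike is detected as exactly one event", {
  series <- simulate_logger(
    n_days = 7,
    spike = list(day = 4, start_hour = 10, excess = 1.0, duration_min = 60)
  )
  events <- detect_spikes(series, delta = 1.0)
  expect_equal(nrow(events), 1L)
  expect_equal(events$duration_min, 60)
  expect_equal(events$peak_excess, 1.0)
  expect_equal(lubridate::hour(events$onset), 10)

  # without the injection, nothing is flagged at the 1 degC threshold
  clean <- simulate_logger(n_days = 7)
  expect_equal(nrow(detect_spikes(clean, delta = 1.0)), 0L)
})

test_that("spike detection guards its preconditions", {
  series <- simulate_logger(n_days = 7)
  expect_error(detect_spikes(series, delta = 0), class = "thermotol_error_spike")
  short <- simulate_logger(n_days = 2)
  expect_error(detect_spikes(short), class = "thermotol_error_spike")
})

test_that("logger validation catches malformed series", {
  series <- simulate_logger(n_days = 2)
  expect_error(
    as_logger_series(dplyr::mutate(series, temp_c = temp_c + 80)),
    class = "thermotol_error_logger"
  )
  dup <- dplyr::bind_rows(series, series[1, ])
  expect_error(as_logger_series(dup), class = "thermotol_error_logger")
  expect_error(
    as_logger_series(series[, c("site_id", "temp_c")]),
    class = "thermotol_error_missing_column"
  )
  # ISO 8601 text timestamps are parsed
  txt <- dplyr::mutate(series, timestamp = format(timestamp, "%Y-%m-%d %H:%M:%S"))
  expect_equal(as_logger_series(txt)$timestamp, series$timestamp)
})
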