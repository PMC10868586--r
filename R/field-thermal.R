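#' Validate and normalise a temperature-logger series
#'
#' Logger exports are expected as one row per reading with columns `site_id`,
#' `timestamp` (POSIXct, or ISO 8601 text parsed in the input's own local
#' clock; no timezone arithmetic is applied) and `temp_c`. Timestamps must be
#' strictly increasing within a site and temperatures must fall in the
#' -5 to 60 degC sanity band for water loggers.
#'
#' @param series A data frame of logger readings.
#' @return A tibble sorted by site and time with POSIXct timestamps.
#' @export
as_logger_series <- function(series) {
  series <- tibble::as_tibble(series)
  required <- c("site_id", "timestamp", "temp_c")
  missing <- setdiff(required, names(series))
  if (length(missing) > 0L) {
    abort(
      sprintf("Logger data is missing required column(s): %s.", toString(missing)),
      class = "thermotol_error_missing_column",
      column = missing
    )
  }
  if (is.character(series$timestamp)) {
    ts <- lubridate::ymd_hms(series$timestamp, tz = "UTC", quiet = TRUE)
    if (anyNA(ts)) {
      abort("Logger timestamps could not be parsed as ISO 8601 date-times.",
        class = "thermotol_error_logger"
      )
    }
    series$timestamp <- ts
  }
  if (!lubridate::is.POSIXct(series$timestamp)) {
    abort("`timestamp` must be POSIXct or ISO 8601 text.",
      class = "thermotol_error_logger"
    )
  }
  if (anyNA(series$temp_c) || any(!is.finite(series$temp_c))) {
    abort("Logger temperatures contain missing or non-finite values.",
      class = "thermotol_error_logger"
    )
  }
  if (any(series$temp_c < -5 | series$temp_c > 60)) {
    abort("Logger temperatures outside the -5..60 degC sanity band.",
      class = "thermotol_error_logger"
    )
  }
  series <- dplyr::arrange(series, .data$site_id, .data$timestamp)
  bad <- series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(.data$timestamp)) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort("Timestamps must be strictly increasing within each site.",
      class = "thermotol_error_logger"
    )
  }
  series
}

# Median sampling interval in minutes, per site.
nominal_interval_min <- function(timestamps) {
  if (length(timestamps) < 2L) {
    return(NA_real_)
  }
  median(diff(as.numeric(timestamps))) / 60
}

#' Daily summaries of a logger series
#'
#' For every civil day (in the input's own clock) with at least two readings,
#' computes the mean, minimum and maximum temperature, the clock times at
#' which the extremes occurred, the sunrise-to-peak heating rate (see
#' [heating_rates()]) and a completeness flag. Days with fewer than 75% of
#' the readings expected at the site's nominal sampling interval are marked
#' `partial` and should be excluded from cross-day averages; days with a
#' single reading are dropped entirely.
#'
#' @param series Logger readings; see [as_logger_series()].
#' @param sunrise_policy,fixed_time Passed to [heating_rates()].
#' @return A tibble with one row per site-day: `site_id`, `date`,
#'   `mean_temp`, `min_temp`, `max_temp`, `time_of_min`, `time_of_max`,
#'   `heating_rate` (degC/min, 3 decimals; `NA` when the maximum precedes
#'   the anchor), `n_samples`, `partial`.
#' @export
daily_summaries <- function(series, sunrise_policy = c("dawn_min", "fixed"),
                            fixed_time = "06:00") {
  series <- as_logger_series(series)
  if (nrow(series) == 0L) {
    return(tibble::tibble(
      site_id = character(), date = as.Date(character()),
      mean_temp = numeric(), min_temp = numeric(), max_temp = numeric(),
      time_of_min = as.POSIXct(character(), tz = "UTC"),
      time_of_max = as.POSIXct(character(), tz = "UTC"),
      heating_rate = numeric(), n_samples = integer(), partial = logical()
    ))
  }
  interval <- series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(interval_min = nominal_interval_min(.data$timestamp), .groups = "drop")

  days <- series |>
    dplyr::mutate(date = lubridate::as_date(.data$timestamp)) |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(
      mean_temp = mean(.data$temp_c),
      min_temp = min(.data$temp_c),
      max_temp = max(.data$temp_c),
      time_of_min = .data$timestamp[which.min(.data$temp_c)],
      time_of_max = .data$timestamp[which.max(.data$temp_c)],
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(interval, by = "site_id") |>
    dplyr::mutate(
      partial = .data$n_samples < 0.75 * (1440 / .data$interval_min)
    )

  dropped <- days[days$n_samples < 2L, ]
  if (nrow(dropped) > 0L) {
    warn(sprintf(
      "Dropped %d day(s) with a single reading: %s.",
      nrow(dropped),
      toString(paste(dropped$site_id, dropped$date), collapse = ", ")
    ))
    days <- days[days$n_samples >= 2L, ]
  }

  rates <- heating_rates(series,
    sunrise_policy = sunrise_policy,
    fixed_time = fixed_time, warn_undefined = FALSE
  )
  days |>
    dplyr::left_join(
      dplyr::select(rates, "site_id", "date", "heating_rate"),
      by = c("site_id", "date")
    ) |>
    dplyr::select(
      "site_id", "date", "mean_temp", "min_temp", "max_temp",
      "time_of_min", "time_of_max", "heating_rate", "n_samples", "partial"
    )
}

#' Sunrise-to-peak habitat heating rates
#'
#' The habitat heating rate of a day is the temperature rise from a sunrise
#' anchor to the daily maximum, divided by the elapsed minutes. True sunrise
#' times are not recorded by the loggers, so two anchor policies are offered:
#'
#' * `"dawn_min"` (default): the reading with the lowest temperature in the
#'   00:00-12:00 window - the dawn minimum is the observable proxy closest
#'   to sunrise in a diel water-temperature cycle.
#' * `"fixed"`: the first reading at or after a fixed local clock time
#'   (default 06:00).
#'
#' Rates are reported to three decimals, matching the precision at which
#' habitat rates of a few thousandths of a degree per minute are
#' distinguishable. When the daily maximum occurs at or before the anchor
#' the rate is undefined and returned as `NA` with a warning.
#'
#' @param series Logger readings; see [as_logger_series()].
#' @param sunrise_policy `"dawn_min"` or `"fixed"`.
#' @param fixed_time Clock time ("HH:MM") for the fixed policy.
#' @param warn_undefined Warn about days with undefined rates (default TRUE).
#' @return A tibble with `site_id`, `date`, `anchor_time`, `anchor_temp`,
#'   `max_time`, `max_temp`, `heating_rate` (degC/min).
#' @export
heating_rates <- function(series, sunrise_policy = c("dawn_min", "fixed"),
                          fixed_time = "06:00", warn_undefined = TRUE) {
  series <- as_logger_series(series)
  sunrise_policy <- match.arg(sunrise_policy)
  fixed_min <- clock_to_minutes(fixed_time)

  out <- series |>
    dplyr::mutate(
      date = lubridate::as_date(.data$timestamp),
      clock_min = lubridate::hour(.data$timestamp) * 60 +
        lubridate::minute(.data$timestamp) +
        lubridate::second(.data$timestamp) / 60
    ) |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::group_modify(~ day_heating_rate(.x, sunrise_policy, fixed_min)) |>
    dplyr::ungroup()

  undef <- is.na(out$heating_rate)
  if (warn_undefined && any(undef)) {
    warn(sprintf(
      "Heating rate undefined (maximum at or before the sunrise anchor) on %d day(s).",
      sum(undef)
    ))
  }
  out
}

day_heating_rate <- function(day, sunrise_policy, fixed_min) {
  i_max <- which.max(day$temp_c)
  if (sunrise_policy == "dawn_min") {
    morning <- which(day$clock_min < 720)
    if (length(morning) == 0L) {
      return(rate_row(day, NA_integer_, i_max))
    }
    i_anchor <- morning[which.min(day$temp_c[morning])]
  } else {
    after <- which(day$clock_min >= fixed_min)
    if (length(after) == 0L) {
      return(rate_row(day, NA_integer_, i_max))
    }
    i_anchor <- after[1L]
  }
  rate_row(day, i_anchor, i_max)
}

rate_row <- function(day, i_anchor, i_max) {
  if (is.na(i_anchor)) {
    return(tibble::tibble(
      anchor_time = day$timestamp[NA_integer_], anchor_temp = NA_real_,
      max_time = day$timestamp[i_max], max_temp = day$temp_c[i_max],
      heating_rate = NA_real_
    ))
  }
  elapsed_min <- as.numeric(difftime(day$timestamp[i_max], day$timestamp[i_anchor],
    units = "mins"
  ))
  rate <- if (elapsed_min > 0) {
    round((day$temp_c[i_max] - day$temp_c[i_anchor]) / elapsed_min, 3)
  } else if (elapsed_min == 0 && day$temp_c[i_max] == day$temp_c[i_anchor]) {
    0 # flat day: max and anchor coincide
  } else {
    NA_real_
  }
  tibble::tibble(
    anchor_time = day$timestamp[i_anchor], anchor_temp = day$temp_c[i_anchor],
    max_time = day$timestamp[i_max], max_temp = day$temp_c[i_max],
    heating_rate = rate
  )
}

clock_to_minutes <- function(clock) {
  parts <- as.numeric(strsplit(clock, ":", fixed = TRUE)[[1L]])
  parts[1L] * 60 + parts[2L]
}

#' Daily time-in-band exposure durations
#'
#' Computes, for each site-day, the number of minutes the (linearly
#' interpolated) water temperature spent inside each half-open band
#' `[lo, hi)`. Band-crossing times are solved exactly on every linear
#' segment, so the result is invariant under resampling of a segment at
#' higher frequency. Segments spanning midnight are split at the day
#' boundary so each day is charged only its own minutes.
#'
#' @param series Logger readings; see [as_logger_series()].
#' @param band_edges Ascending band boundaries in degC (default `32:36`,
#'   giving four 1-degree bands over the range of observed habitat maxima).
#' @return A tibble with `site_id`, `date`, `band_lo`, `band_hi`, `minutes`.
#'   Summarise across days with [summarise_exposure()].
#' @export
exposure_durations <- function(series, band_edges = 32:36) {
  series <- as_logger_series(series)
  check_band_edges(band_edges)
  lo <- head(band_edges, -1L)
  hi <- tail(band_edges, -1L)

  segs <- series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::reframe(day_segments(.data$timestamp, .data$temp_c))
  if (nrow(segs) == 0L) {
    return(tibble::tibble(
      site_id = character(), date = as.Date(character()),
      band_lo = numeric(), band_hi = numeric(), minutes = numeric()
    ))
  }

  bands <- tibble::tibble(band_lo = lo, band_hi = hi)
  dplyr::cross_join(segs, bands) |>
    dplyr::mutate(minutes = segment_band_minutes(
      .data$dur_min, .data$x0, .data$x1, .data$band_lo, .data$band_hi
    )) |>
    dplyr::group_by(.data$site_id, .data$date, .data$band_lo, .data$band_hi) |>
    dplyr::summarise(minutes = sum(.data$minutes), .groups = "drop")
}

# Split a site's readings into linear segments, cutting at midnight so each
# segment belongs to exactly one civil day.
day_segments <- function(timestamp, temp) {
  if (length(timestamp) < 2L) {
    return(tibble::tibble(
      date = as.Date(character()), dur_min = numeric(),
      x0 = numeric(), x1 = numeric()
    ))
  }
  t0 <- head(timestamp, -1L)
  t1 <- tail(timestamp, -1L)
  x0 <- head(temp, -1L)
  x1 <- tail(temp, -1L)
  rows <- purrr::pmap(list(t0, t1, x0, x1), split_segment_at_midnight)
  dplyr::bind_rows(rows)
}

split_segment_at_midnight <- function(t0, t1, x0, x1) {
  d0 <- lubridate::as_date(t0)
  d1 <- lubridate::as_date(t1)
  if (d0 == d1) {
    return(tibble::tibble(
      date = d0,
      dur_min = as.numeric(difftime(t1, t0, units = "mins")),
      x0 = x0, x1 = x1
    ))
  }
  cuts <- lubridate::as_datetime(seq(d0 + 1, d1, by = "1 day"), tz = lubridate::tz(t0))
  knots <- c(t0, cuts, t1)
  frac <- as.numeric(difftime(knots, t0, units = "mins")) /
    as.numeric(difftime(t1, t0, units = "mins"))
  temps <- x0 + (x1 - x0) * frac
  tibble::tibble(
    date = lubridate::as_date(head(knots, -1L)),
    dur_min = as.numeric(difftime(tail(knots, -1L), head(knots, -1L), units = "mins")),
    x0 = head(temps, -1L),
    x1 = tail(temps, -1L)
  )
}

# Minutes a linear segment of duration dur_min from x0 to x1 spends inside
# the half-open band [lo, hi). Vectorised.
segment_band_minutes <- function(dur_min, x0, x1, lo, hi) {
  flat <- x0 == x1
  out <- numeric(length(dur_min))
  out[flat] <- dur_min[flat] * (x0[flat] >= lo[flat] & x0[flat] < hi[flat])
  if (any(!flat)) {
    i <- !flat
    xmin <- pmin(x0[i], x1[i])
    xmax <- pmax(x0[i], x1[i])
    overlap <- pmax(0, pmin(xmax, hi[i]) - pmax(xmin, lo[i]))
    out[i] <- dur_min[i] * overlap / (xmax - xmin)
  }
  out
}

#' Mean and spread of daily exposure per band
#'
#' Averages the per-day band durations of [exposure_durations()] across days,
#' per site and band.
#'
#' @param exposure Output of [exposure_durations()].
#' @return A tibble with `site_id`, `band_lo`, `band_hi`, `mean_minutes`,
#'   `sd_minutes`, `n_days`.
#' @export
summarise_exposure <- function(exposure) {
  exposure |>
    dplyr::group_by(.data$site_id, .data$band_lo, .data$band_hi) |>
    dplyr::summarise(
      mean_minutes = mean(.data$minutes),
      sd_minutes = sd(.data$minutes),
      n_days = dplyr::n(),
      .groups = "drop"
    )
}

#' Detect transient heat-spike events against a diel baseline
#'
#' Flags readings that exceed the site's typical temperature for that hour of
#' day by at least `delta` degC. The baseline for a reading is the median of
#' the site's temperatures recorded at the same hour on *other* days, so a
#' sustained diel cycle is not flagged while a one-off excursion (such as a
#' sudden release of heated water) is. Consecutive exceeding readings within
#' `window` minutes of each other are merged into one event.
#'
#' @param series Logger readings; see [as_logger_series()].
#' @param delta Minimum excess over baseline, degC; must be > 0. The default
#'   1.0 degC corresponds to the magnitude of transient river-heating events
#'   that have caused fish mass mortality.
#' @param window Maximum gap (minutes) between exceeding readings merged into
#'   a single event; defaults to 90 (one hourly reading may be missed).
#' @return A tibble with one row per event: `site_id`, `onset`, `end`,
#'   `duration_min` (number of exceeding readings times the site's nominal
#'   sampling interval), `peak_excess`, `n_samples`.
#' @export
detect_spikes <- function(series, delta = 1.0, window = 90) {
  series <- as_logger_series(series)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    abort("`delta` must be a positive excess in degC; delta <= 0 would flag ordinary noise.",
      class = "thermotol_error_spike"
    )
  }
  series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(~ site_spikes(.x, delta, window)) |>
    dplyr::ungroup()
}

site_spikes <- function(x, delta, window) {
  x <- dplyr::mutate(x,
    date = lubridate::as_date(.data$timestamp),
    hour = lubridate::hour(.data$timestamp)
  )
  if (length(unique(x$date)) < 3L) {
    abort("baseline undefined: need at least 3 days of data per site.",
      class = "thermotol_error_spike"
    )
  }
  interval <- nominal_interval_min(x$timestamp)
  # leave-one-day-out median by hour of day
  baseline <- vapply(seq_len(nrow(x)), function(i) {
    same_hour <- x$hour == x$hour[i] & x$date != x$date[i]
    median(x$temp_c[same_hour])
  }, numeric(1))
  excess <- x$temp_c - baseline
  # tolerance absorbs representation error when the excess equals delta
  hit <- !is.na(excess) & excess >= delta - 1e-9
  if (!any(hit)) {
    return(tibble::tibble(
      onset = x$timestamp[0], end = x$timestamp[0],
      duration_min = numeric(), peak_excess = numeric(), n_samples = integer()
    ))
  }
  idx <- which(hit)
  gap <- c(Inf, diff(as.numeric(x$timestamp[idx])) / 60)
  event_id <- cumsum(gap > window)
  tibble::tibble(idx = idx, event_id = event_id) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      onset = x$timestamp[min(.data$idx)],
      end = x$timestamp[max(.data$idx)],
      duration_min = dplyr::n() * interval,
      peak_excess = max(excess[.data$idx]),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"event_id")
}
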