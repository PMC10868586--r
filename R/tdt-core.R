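#' Tolerable exposure time at a constant temperature
#'
#' Evaluates the thermal death time curve: the duration for which a constant
#' temperature can be endured before knockdown,
#' `t_ref * 10^((t_static - temp) / z)`. The curve is strictly decreasing in
#' temperature; well below `t_static` the returned durations become
#' astronomically large, which is meaningful (cold temperatures are tolerated
#' essentially indefinitely on the heat-injury scale) and returned as-is.
#'
#' @param params A [tdt_params()] object (or a fitted `tdt_fit`).
#' @param temp Temperature(s) in degrees C. Vectorised.
#' @return Tolerable duration(s) in minutes.
#' @examples
#' p <- tdt_params(z = 4.19, t_static = 39)
#' tolerable_time(p, 34) # about 15.6 min
#' @export
tolerable_time <- function(params, temp) {
  params <- as_tdt_params(params)
  stopifnot(is.numeric(temp))
  params$t_ref * 10^((params$t_static - temp) / params$z)
}

#' Accumulated heat injury along a temperature trajectory
#'
#' Integrates the instantaneous injury rate `1 / tolerable_time(T(t))` over a
#' time-ordered trajectory; knockdown is predicted when the accumulated
#' injury reaches 1. Between samples the temperature is interpolated
#' linearly, and each linear segment is integrated in closed form (the
#' integral of an exponential in time). A composite-Simpson fallback at
#' 0.01-minute resolution is available for cross-checking.
#'
#' Injury is additive over concatenated trajectories: splitting a trajectory
#' at any sample point and summing the two integrals reproduces the total.
#'
#' @param params A [tdt_params()] object.
#' @param trajectory A data frame whose first two columns are time in minutes
#'   and temperature in degrees C (columns named `time_min` and `temp_c` are
#'   used when present). Times must be strictly increasing and at least two
#'   samples are required.
#' @param method `"closed_form"` (default, exact per linear segment) or
#'   `"simpson"` (numeric quadrature at 0.01-min steps).
#' @return A single non-negative number: the accumulated injury
#'   (dimensionless; 1 = knockdown).
#' @examples
#' p <- tdt_params(z = 5.58, t_static = 41.4)
#' # one reference duration at the static limit accumulates exactly 1
#' injury_integral(p, data.frame(time_min = c(0, 1), temp_c = c(41.4, 41.4)))
#' @export
injury_integral <- function(params, trajectory,
                            method = c("closed_form", "simpson")) {
  params <- as_tdt_params(params)
  method <- match.arg(method)
  traj <- as.data.frame(trajectory)
  if (all(c("time_min", "temp_c") %in% names(traj))) {
    time <- traj$time_min
    temp <- traj$temp_c
  } else {
    time <- traj[[1L]]
    temp <- traj[[2L]]
  }
  if (length(time) < 2L) {
    abort("A trajectory needs at least two (time, temperature) samples.",
      class = "thermotol_error_trajectory"
    )
  }
  if (any(diff(time) <= 0)) {
    abort("Trajectory timestamps must be strictly increasing.",
      class = "thermotol_error_trajectory"
    )
  }
  if (anyNA(time) || anyNA(temp)) {
    abort("Trajectory contains missing values.", class = "thermotol_error_trajectory")
  }
  t0 <- head(time, -1L)
  t1 <- tail(time, -1L)
  x0 <- head(temp, -1L)
  x1 <- tail(temp, -1L)
  if (method == "closed_form") {
    sum(segment_injury(params, t1 - t0, x0, x1))
  } else {
    sum(vapply(
      seq_along(t0),
      function(i) simpson_segment_injury(params, t1[i] - t0[i], x0[i], x1[i]),
      numeric(1)
    ))
  }
}

# Exact injury for a linear temperature segment of duration dt from x0 to x1:
# integral of 10^((T(t) - t_static)/z) / t_ref dt. Vectorised over segments.
segment_injury <- function(params, dt, x0, x1) {
  z <- params$z
  ts <- params$t_static
  tr <- params$t_ref
  rate <- (x1 - x0) / dt
  flat <- abs(x1 - x0) < 1e-12
  out <- numeric(length(dt))
  if (any(flat)) {
    out[flat] <- dt[flat] * 10^((x0[flat] - ts) / z) / tr
  }
  if (any(!flat)) {
    i <- !flat
    out[i] <- z / (rate[i] * log(10) * tr) *
      (10^((x1[i] - ts) / z) - 10^((x0[i] - ts) / z))
  }
  out
}

simpson_segment_injury <- function(params, dt, x0, x1, step = 0.01) {
  n <- max(2L, ceiling(dt / step))
  if (n %% 2L == 1L) n <- n + 1L
  tt <- seq(0, dt, length.out = n + 1L)
  temp <- x0 + (x1 - x0) * tt / dt
  f <- 10^((temp - params$t_static) / params$z) / params$t_ref
  h <- dt / n
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f) * h / 3
}

#' Knockdown temperature under a constant heating ramp
#'
#' Solves the injury-accumulation equation for a linear ramp starting at
#' `start_temp` and heated at `heating_rate` degrees C per minute: the
#' knockdown temperature `Tk` satisfies
#' `(z / (r * ln10 * t_ref)) * (10^((Tk - t_static)/z) - 10^((start - t_static)/z)) = 1`,
#' giving the closed form
#' `Tk = t_static + z * log10(r * ln10 * t_ref / z + 10^((start - t_static)/z))`.
#' Faster ramps and warmer starts both give higher knockdown temperatures.
#'
#' This is the dynamic-assay prediction of the TDT framework: it converts the
#' static tolerance curve into the CTmax that a ramping trial at a given
#' heating rate would record.
#'
#' @param params A [tdt_params()] object.
#' @param start_temp Ramp start temperature(s), degrees C. Vectorised.
#' @param heating_rate Ramp rate(s), degrees C per minute; must be > 0.
#' @return Knockdown temperature(s) in degrees C.
#' @examples
#' p <- tdt_params(z = 5.58, t_static = 41.4)
#' dynamic_knockdown(p, start_temp = 30, heating_rate = c(0.003, 0.42))
#' @export
dynamic_knockdown <- function(params, start_temp, heating_rate) {
  params <- as_tdt_params(params)
  stopifnot(is.numeric(start_temp), is.numeric(heating_rate))
  if (any(!is.finite(heating_rate)) || any(heating_rate <= 0)) {
    abort("`heating_rate` must be positive (degrees C per minute).",
      class = "thermotol_error_rate"
    )
  }
  z <- params$z
  ts <- params$t_static
  tr <- params$t_ref
  start_injury_rate <- 10^((start_temp - ts) / z) # relative to 1/t_ref
  if (any(start_injury_rate > 0.5)) {
    warn(paste(
      "Ramp start temperature is already close to the static limit:",
      "injury accumulates appreciably before heating begins."
    ))
  }
  ts + z * log10(heating_rate * log(10) * tr / z + start_injury_rate)
}

#' Predicted CTmax at a habitat heating rate
#'
#' A labelled alias of [dynamic_knockdown()] for field use: given a fitted
#' tolerance curve and the slow sunrise-to-peak heating rate observed at a
#' site, returns the CTmax a dynamic trial run at that rate would record.
#' Because habitat rates (thousandths of a degree per minute) are far below
#' laboratory ramp rates (~0.4 degC/min), predicted field CTmax values sit
#' below laboratory CTmax values.
#'
#' @param params A [tdt_params()] object or `tdt_fit`.
#' @param site_rate Observed heating rate(s) at the site, degC/min.
#' @param site_start Ramp start temperature(s) at the site, degC (typically
#'   the dawn minimum).
#' @param site_id Optional site label(s), recycled against the rates.
#' @return A tibble with columns `site_id`, `heating_rate`, `start_temp`,
#'   `predicted_ctmax`, shaped for site-by-site reporting.
#' @export
predict_ctmax_at_rate <- function(params, site_rate, site_start, site_id = NULL) {
  params <- as_tdt_params(params)
  n <- max(length(site_rate), length(site_start))
  site_id <- site_id %||% paste0("site_", seq_len(n))
  tibble::tibble(
    site_id = rep_len(as.character(site_id), n),
    heating_rate = rep_len(site_rate, n),
    start_temp = rep_len(site_start, n),
    predicted_ctmax = dynamic_knockdown(params,
      start_temp = rep_len(site_start, n),
      heating_rate = rep_len(site_rate, n)
    )
  )
}

#' Tolerable exposure times over a temperature band
#'
#' Convenience wrapper evaluating [tolerable_time()] at the midpoints of
#' half-open 1-degree bands (default 32-36 degC, the range of habitat
#' maxima), for comparison against observed time-in-band exposure.
#'
#' @param params A [tdt_params()] object or `tdt_fit`.
#' @param band_edges Ascending band edges in degC; bands are `[lo, hi)`.
#' @param species Optional species label carried into the output.
#' @return A tibble with `band_lo`, `band_hi`, `band_mid`,
#'   `tolerable_min` (strictly decreasing across ascending bands).
#' @export
tolerable_times_by_band <- function(params, band_edges = 32:36, species = NA_character_) {
  params <- as_tdt_params(params)
  check_band_edges(band_edges)
  lo <- head(band_edges, -1L)
  hi <- tail(band_edges, -1L)
  mid <- (lo + hi) / 2
  tibble::tibble(
    species = species,
    band_lo = lo,
    band_hi = hi,
    band_mid = mid,
    tolerable_min = tolerable_time(params, mid)
  )
}

check_band_edges <- function(band_edges) {
  if (!is.numeric(band_edges) || length(band_edges) < 2L ||
    any(!is.finite(band_edges)) || any(diff(band_edges) <= 0)) {
    abort("`band_edges` must be an ascending numeric vector of band boundaries.",
      class = "thermotol_error_bands"
    )
  }
  invisible(band_edges)
}
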