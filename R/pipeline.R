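#' Fit TDT curves per species from a trial table
#'
#' Groups a trial table by species (and oxygen treatment when present) and
#' fits one TDT curve per group with [fit_tdt()]. This is the batch entry
#' point behind the command-line `fit` subcommand.
#'
#' @param trials A trial tibble ([read_trials()] / [trial_summaries()]).
#' @param t_ref Reference duration, minutes.
#' @return A named list of `tdt_fit` objects, one per species (names
#'   `species` or `species.oxygen`).
#' @export
run_fit <- function(trials, t_ref = 1) {
  trials <- normalise_trials(trials)
  keys <- intersect(c("species", "oxygen"), names(trials))
  if (length(keys) == 0L) {
    return(list(fit = fit_tdt(trials, t_ref = t_ref)))
  }
  split_tbl <- dplyr::group_split(dplyr::group_by(
    trials,
    dplyr::across(dplyr::all_of(keys))
  ))
  # lapply, not purrr::map: classed fit errors must reach the caller intact
  fits <- lapply(split_tbl, fit_tdt, t_ref = t_ref)
  names(fits) <- purrr::map_chr(split_tbl, function(d) {
    paste(purrr::map_chr(keys, ~ as.character(d[[.x]][1L])), collapse = ".")
  })
  fits
}

#' Predict field CTmax and tolerable exposure times
#'
#' Applies fitted TDT parameters to habitat conditions: predicted CTmax for
#' each site's observed heating rate (Table-2-shaped) and tolerable exposure
#' durations at the midpoints of the 32-36 degC bands (Fig.-3-shaped).
#' Sites with non-positive heating rates produce an error record but do not
#' stop the run.
#'
#' @param fits A named list of `tdt_fit`/`tdt_params` (names = group label),
#'   as from [run_fit()] or [read_fit_yaml()].
#' @param sites A tibble with `site_id`, `heating_rate` (degC/min) and
#'   `start_temp` (degC; typically the dawn minimum temperature).
#' @param band_edges Ascending band edges, degC (default `32:36`).
#' @return A list with `predicted_ctmax` (species x site tibble; rows with
#'   invalid rates carry `NA` and an `error` message), and
#'   `tolerable_times` (species x band tibble).
#' @export
run_predict <- function(fits, sites, band_edges = 32:36) {
  sites <- tibble::as_tibble(sites)
  require_columns(sites, c("site_id", "heating_rate", "start_temp"), "site table")
  preds <- purrr::imap_dfr(fits, function(f, label) {
    p <- as_tdt_params(f)
    ok <- is.finite(sites$heating_rate) & sites$heating_rate > 0
    res <- tibble::tibble(
      species = label,
      site_id = as.character(sites$site_id),
      heating_rate = sites$heating_rate,
      start_temp = sites$start_temp,
      predicted_ctmax = NA_real_,
      error = dplyr::if_else(ok, NA_character_, "heating_rate must be > 0")
    )
    if (any(ok)) {
      res$predicted_ctmax[ok] <- dynamic_knockdown(
        p, sites$start_temp[ok], sites$heating_rate[ok]
      )
    }
    res
  })
  times <- purrr::imap_dfr(fits, function(f, label) {
    tolerable_times_by_band(as_tdt_params(f), band_edges, species = label)
  })
  list(predicted_ctmax = preds, tolerable_times = times)
}

#' Compare observed exposure against tolerable exposure
#'
#' Joins the mean observed daily time-in-band at each site with the model's
#' tolerable duration for that band and issues a verdict: `EXCEEDS` when the
#' observed mean strictly exceeds the tolerable duration (ties are
#' conservatively "within tolerance").
#'
#' @param exposure Per-site band exposure summary ([summarise_exposure()]),
#'   with `site_id`, `band_lo`, `band_hi`, `mean_minutes`.
#' @param tolerable_times Species band predictions from [run_predict()].
#' @return A tibble with one row per site x band x species: observed and
#'   tolerable minutes plus a logical `exceeds` and text `verdict`.
#' @export
run_compare <- function(exposure, tolerable_times) {
  exposure <- tibble::as_tibble(exposure)
  tolerable_times <- tibble::as_tibble(tolerable_times)
  require_columns(exposure, c("site_id", "band_lo", "band_hi", "mean_minutes"), "exposure table")
  require_columns(
    tolerable_times, c("species", "band_lo", "band_hi", "tolerable_min"),
    "tolerable-times table"
  )
  obs_bands <- dplyr::distinct(exposure, .data$band_lo, .data$band_hi)
  pred_bands <- dplyr::distinct(tolerable_times, .data$band_lo, .data$band_hi)
  if (!identical(
    dplyr::arrange(obs_bands, .data$band_lo),
    dplyr::arrange(pred_bands, .data$band_lo)
  )) {
    abort("Band definitions differ between the exposure and tolerable-times tables.",
      class = "thermotol_error_bands"
    )
  }
  dplyr::inner_join(exposure, tolerable_times,
    by = c("band_lo", "band_hi"), relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      exceeds = .data$mean_minutes > .data$tolerable_min,
      verdict = dplyr::if_else(.data$exceeds, "EXCEEDS", "WITHIN")
    ) |>
    dplyr::select(
      "site_id", "species", "band_lo", "band_hi",
      observed_min = "mean_minutes", "tolerable_min", "exceeds", "verdict"
    ) |>
    dplyr::arrange(.data$site_id, .data$species, .data$band_lo)
}

#' Run the full synthetic pipeline
#'
#' Simulate assays and a logger series, fit the TDT curve on trial means,
#' predict field CTmax and tolerable times at the observed site heating
#' rates, and compare against observed exposure - the whole analysis from a
#' single seed, in memory.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_days Days of logger data to simulate.
#' @param band_edges Band edges for the exposure comparison.
#' @return A list: `records`, `trials`, `fit`, `logger`, `daily`,
#'   `exposure`, `predictions`, `verdicts`.
#' @export
run_pipeline <- function(seed = 1, n_days = 14, band_edges = 32:36) {
  records <- simulate_assay(
    n_trials = 4, n_fish = 12, z = 5.58,
    t_static = t_static_for_ctmax(5.58, 39.2, 26, 0.42),
    heating_rate = 0.39, rate_sd = 0.05, start_temp = 26,
    between_fish_sd = 0.5, seed = seed
  )
  trials <- trial_summaries(records)
  fit <- suppressWarnings(fit_tdt(trials))
  logger <- simulate_logger(
    n_days = n_days, obs_noise_sd = 0.1,
    seed = seed + 1000L
  )
  daily <- daily_summaries(logger)
  exposure <- exposure_durations(logger, band_edges)
  sites <- daily |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      heating_rate = mean(.data$heating_rate, na.rm = TRUE),
      start_temp = mean(.data$min_temp),
      .groups = "drop"
    )
  predictions <- run_predict(list("P. sulphuraria" = fit), sites, band_edges)
  verdicts <- run_compare(summarise_exposure(exposure), predictions$tolerable_times)
  list(
    records = records, trials = trials, fit = fit, logger = logger,
    daily = daily, exposure = exposure, predictions = predictions,
    verdicts = verdicts
  )
}
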