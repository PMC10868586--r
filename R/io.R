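#' Read and write the package's delimited formats
#'
#' Thin readr wrappers for the three tabular inputs (individual assay
#' records, per-trial summaries, logger exports) and for the tabular
#' outputs. Column-name contracts:
#'
#' * `assays.csv`: `fish_id, species, oxygen, trial_id, direction,
#'   knockdown_temp_c, standard_length_mm, collection_temp_c`
#' * `trials.csv`: `trial_id, species, oxygen, heating_rate_c_per_min,
#'   start_temp_c, mean_knockdown_c, n_fish`
#' * `logger.csv`: `site_id, timestamp` (ISO 8601 local), `temp_c`
#'
#' @param path File path.
#' @return A tibble; logger series are validated with [as_logger_series()].
#' @name thermotol_io
NULL

#' @rdname thermotol_io
#' @export
read_assays <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(x, c(
    "fish_id", "species", "oxygen", "trial_id", "direction",
    "knockdown_temp_c", "collection_temp_c"
  ), "assay file")
  x
}

#' @rdname thermotol_io
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(
    x,
    c("trial_id", "species", "oxygen", "heating_rate_c_per_min", "start_temp_c", "mean_knockdown_c"),
    "trial file"
  )
  dplyr::rename(x,
    heating_rate = "heating_rate_c_per_min",
    start_temp = "start_temp_c",
    mean_knockdown = "mean_knockdown_c"
  )
}

#' @rdname thermotol_io
#' @export
read_logger <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(x, c("site_id", "timestamp", "temp_c"), "logger file")
  as_logger_series(x)
}

require_columns <- function(x, cols, what) {
  if (nrow(x) == 0L && ncol(x) == 0L) {
    abort(sprintf("The %s is empty.", what),
      class = "thermotol_error_missing_column", column = cols
    )
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort(
      sprintf("The %s is missing required column(s): %s.", what, toString(missing)),
      class = "thermotol_error_missing_column", column = missing
    )
  }
  invisible(x)
}

#' Serialise a TDT fit to YAML
#'
#' Writes the fitted parameters and diagnostics of one or more [fit_tdt()]
#' objects as a YAML document, one block per species/oxygen group.
#'
#' @param fits A named list of `tdt_fit` objects (names are group labels),
#'   or a single fit.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_yaml <- function(fits, path) {
  if (inherits(fits, "tdt_fit")) fits <- list(fit = fits)
  blocks <- purrr::map(fits, function(f) {
    d <- f$data
    list(
      species = if ("species" %in% names(d)) as.character(d$species[1L]) else NA,
      oxygen = if ("oxygen" %in% names(d)) as.character(d$oxygen[1L]) else NA,
      z = round(f$params$z, 4),
      t_static = round(f$params$t_static, 4),
      t_ref_min = f$params$t_ref,
      rss = signif(f$rss, 6),
      n_trials = f$n_trials,
      rate_spread = round(f$rate_spread, 4),
      warnings = as.list(f$warnings)
    )
  })
  yaml::write_yaml(blocks, path)
  invisible(path)
}

#' Read a TDT fit back from YAML
#'
#' @param path A YAML file written by [write_fit_yaml()].
#' @return A named list of [tdt_params()] objects.
#' @export
read_fit_yaml <- function(path) {
  blocks <- yaml::read_yaml(path)
  purrr::map(blocks, function(b) {
    suppressWarnings(tdt_params(z = b$z, t_static = b$t_static, t_ref = b$t_ref_min))
  })
}
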