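#' Thermal death time (TDT) parameters
#'
#' Bundles the two parameters of a thermal death time curve together with the
#' reference exposure duration they are anchored to. The TDT curve relates a
#' constant stress temperature to the time an animal endures it before
#' knockdown:
#'
#' \deqn{\log_{10}(t / t_{ref}) = (T_{static} - T) / z}
#'
#' so `t_static` is the constant temperature producing knockdown at exactly
#' `t_ref` minutes (the "1-minute CTmax" under the default), and `z` is the
#' heat-sensitivity coefficient: the temperature increase that divides
#' tolerable exposure time by ten.
#'
#' @param z Heat-sensitivity coefficient, in degrees C per log10(minute).
#'   Must be a positive finite scalar. Values above 20 indicate a nearly
#'   rate-insensitive (and usually misfitted) curve and trigger a warning.
#' @param t_static Static thermal limit, in degrees C, at the reference
#'   duration. Values outside the 20-50 degrees C band plausible for fish are
#'   warned about but accepted.
#' @param t_ref Reference exposure duration in minutes (default 1).
#'
#' @return An object of class `tdt_params`: a named list with elements `z`,
#'   `t_static` and `t_ref`.
#'
#' @examples
#' p <- tdt_params(z = 5.58, t_static = 41.4)
#' tolerable_time(p, 35.82) # 10 minutes
#' @export
tdt_params <- function(z, t_static, t_ref = 1) {
  check_number(z, "z")
  check_number(t_static, "t_static")
  check_number(t_ref, "t_ref")
  if (z <= 0) {
    abort("`z` must be > 0 (degrees C per log10 minute).",
      class = "thermotol_error_params"
    )
  }
  if (t_ref <= 0) {
    abort("`t_ref` must be a positive duration in minutes.",
      class = "thermotol_error_params"
    )
  }
  if (z > 20) {
    warn(sprintf(
      "z = %.3g is suspiciously large: the tolerance curve is nearly flat in temperature.", z
    ))
  }
  if (t_static < 20 || t_static > 50) {
    warn(sprintf(
      "t_static = %.3g degC lies outside the plausibility band 20-50 degC.", t_static
    ))
  }
  structure(
    list(z = z, t_static = t_static, t_ref = t_ref),
    class = "tdt_params"
  )
}

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
      class = "thermotol_error_params"
    )
  }
  invisible(x)
}

#' @export
print.tdt_params <- function(x, ...) {
  cat("<tdt_params>\n")
  cat(sprintf("  z        : %.4g degC per log10(min)\n", x$z))
  cat(sprintf("  t_static : %.4g degC at t_ref = %.4g min\n", x$t_static, x$t_ref))
  invisible(x)
}

as_tdt_params <- function(x) {
  if (inherits(x, "tdt_params")) {
    return(x)
  }
  if (inherits(x, "tdt_fit")) {
    return(x$params)
  }
  abort("Expected a `tdt_params` object (see `tdt_params()`) or a `tdt_fit`.",
    class = "thermotol_error_params"
  )
}
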