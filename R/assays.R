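#' Trial-blocked marginal means of a factorial assay
#'
#' Computes cell means for a factorial CTmax/CTmin design in which fish are
#' nested in trials (a trial is one ramp of the test tank, so fish within a
#' trial are not independent). The cell mean is the *unweighted mean of
#' trial means* - the trial is the blocking unit - alongside the pooled
#' per-fish mean and the individual minimum and maximum, which differ from
#' the blocked mean whenever trials are unbalanced.
#'
#' @param records A data frame of individual assay records with columns
#'   `species`, `oxygen`, `trial_id` and `knockdown_temp_c` (extra columns
#'   such as `fish_id`, `direction`, `standard_length_mm` are ignored).
#' @param factors Character vector of grouping columns defining the cells
#'   (default `c("species", "oxygen")`).
#' @return A tibble with one row per cell: the factor columns plus
#'   `mean_blocked` (mean of trial means), `mean_pooled` (mean over fish),
#'   `min_individual`, `max_individual`, `n_fish`, `n_trials`.
#' @export
marginal_means <- function(records, factors = c("species", "oxygen")) {
  records <- tibble::as_tibble(records)
  required <- c(factors, "trial_id", "knockdown_temp_c")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    abort(
      sprintf("Assay records are missing required column(s): %s.", toString(missing)),
      class = "thermotol_error_missing_column", column = missing
    )
  }
  full_grid <- tidyr::expand_grid(!!!purrr::map(
    setNames(factors, factors),
    ~ unique(records[[.x]])
  ))
  observed <- dplyr::distinct(records, dplyr::across(dplyr::all_of(factors)))
  empty <- dplyr::anti_join(full_grid, observed, by = factors)
  if (nrow(empty) > 0L) {
    abort(
      sprintf(
        "Empty design cell(s): %s.",
        paste(apply(empty, 1L, paste, collapse = " x "), collapse = "; ")
      ),
      class = "thermotol_error_empty_cell"
    )
  }
  trial_means <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(factors, "trial_id")))) |>
    dplyr::summarise(
      trial_mean = mean(.data$knockdown_temp_c),
      n_fish = dplyr::n(),
      .groups = "drop"
    )
  cells <- trial_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::summarise(
      mean_blocked = mean(.data$trial_mean),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  pooled <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::summarise(
      mean_pooled = mean(.data$knockdown_temp_c),
      min_individual = min(.data$knockdown_temp_c),
      max_individual = max(.data$knockdown_temp_c),
      n_fish = dplyr::n(),
      .groups = "drop"
    )
  dplyr::left_join(cells, pooled, by = factors) |>
    dplyr::select(
      dplyr::all_of(factors), "mean_blocked", "mean_pooled",
      "min_individual", "max_individual", "n_fish", "n_trials"
    )
}

#' Permutation test for a species-by-oxygen interaction
#'
#' Tests whether the effect of the oxygen treatment on knockdown temperature
#' differs between two species. The observed statistic is the
#' difference-in-differences of trial-blocked means,
#' `(mean(sp1, hypoxic) - mean(sp1, normoxic)) - (mean(sp2, hypoxic) - mean(sp2, normoxic))`,
#' with species ordered alphabetically and the oxygen contrast taken
#' alphabetically as well (so with levels `hypoxic`/`normoxic` the contrast
#' is hypoxic minus normoxic). The null distribution is built by permuting
#' oxygen labels within each species: the species' fish are shuffled across
#' its fixed trial-by-oxygen design slots (trial sizes and the number of
#' trials per treatment are preserved) and the trial-blocked contrast is
#' recomputed. The p-value uses the add-one rule
#' `p = (1 + #(|null| >= |obs|)) / (n_perm + 1)` and is two-sided.
#'
#' This randomisation test replaces a mixed model with trial as a random
#' effect: it exercises the same scientific question (does the interaction
#' exist?) without a parametric variance model. Fish-level shuffling assumes
#' fish are exchangeable across a species' trials under the null; a strong
#' between-trial (tank) effect beyond the treatment would make it
#' anti-conservative, which is the same exchangeability caveat that applies
#' to pooling trials in any two-sample randomisation test.
#'
#' @param records Individual assay records; see [marginal_means()]. Exactly
#'   two species and two oxygen levels must be present, every cell
#'   non-empty, and each species needs at least two trials.
#' @param n_perm Number of label permutations (default 999; must be >= 999).
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @return A one-row tibble: `estimate` (observed interaction contrast,
#'   degC), `p_value`, `n_perm`, `n_trials`.
#' @export
interaction_permutation_test <- function(records, n_perm = 999, seed = NULL) {
  if (n_perm < 999) {
    abort("`n_perm` must be at least 999 for a stable permutation p-value.",
      class = "thermotol_error_perm"
    )
  }
  cells <- marginal_means(records) # validates non-empty 2x2 cells
  species <- sort(unique(cells$species))
  oxy <- sort(unique(cells$oxygen))
  if (length(species) != 2L || length(oxy) != 2L) {
    abort("The interaction test needs exactly two species and two oxygen levels.",
      class = "thermotol_error_perm"
    )
  }
  records <- tibble::as_tibble(records)
  # per-species fixed design: fish values plus the trial slot each value
  # occupies; permutations shuffle values across slots within the species
  prep <- purrr::map(setNames(species, species), function(s) {
    r <- records[records$species == s, ]
    trial <- factor(r$trial_id)
    if (nlevels(trial) < 2L) {
      abort("no permutation support: each species needs at least two trials.",
        class = "thermotol_error_perm"
      )
    }
    trial_oxy <- tapply(as.character(r$oxygen), trial, `[`, 1L)
    list(
      v = r$knockdown_temp_c,
      idx = as.integer(trial),
      counts = tabulate(as.integer(trial)),
      second = unname(trial_oxy == oxy[2L]) # trials at the 2nd sorted level
    )
  })
  # oxygen contrast: second sorted level minus first, on trial-blocked means
  species_contrast <- function(pr, v) {
    tm <- rowsum(v, pr$idx) / pr$counts
    mean(tm[pr$second]) - mean(tm[!pr$second])
  }
  obs <- species_contrast(prep[[1L]], prep[[1L]]$v) -
    species_contrast(prep[[2L]], prep[[2L]]$v)
  # paper-facing convention: hypoxic-minus-normoxic difference of species 1
  # minus species 2; with sorted levels this flips sign when the second
  # sorted oxygen level is normoxic
  estimate <- if (oxy[2L] == "normoxic") -obs else obs

  runner <- function() {
    vapply(seq_len(n_perm), function(b) {
      species_contrast(prep[[1L]], sample(prep[[1L]]$v)) -
        species_contrast(prep[[2L]], sample(prep[[2L]]$v))
    }, numeric(1))
  }
  null <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())

  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  tibble::tibble(
    estimate = estimate,
    p_value = p,
    n_perm = as.integer(n_perm),
    n_trials = sum(vapply(prep, function(pr) length(pr$counts), integer(1)))
  )
}

#' Thermal tolerance breadth
#'
#' The broad-sense tolerance range of a treatment group: mean CTmax minus
#' mean CTmin, reported to one decimal (half away from zero).
#'
#' @param ctmax_mean,ctmin_mean Mean critical maximum and minimum
#'   temperatures, degC. Vectorised; `ctmax_mean` must exceed `ctmin_mean`.
#' @return Breadth(s) in degC, one decimal.
#' @examples
#' tolerance_breadth(41.4, 15.9) # 25.5
#' @export
tolerance_breadth <- function(ctmax_mean, ctmin_mean) {
  stopifnot(is.numeric(ctmax_mean), is.numeric(ctmin_mean))
  if (any(ctmax_mean <= ctmin_mean)) {
    abort("`ctmax_mean` must exceed `ctmin_mean`.", class = "thermotol_error_breadth")
  }
  round_half_out(ctmax_mean - ctmin_mean, 1L)
}

#' Thermal safety margin
#'
#' The margin between a tolerance limit and the warmest water the animals
#' actually experienced: `ctmax - t_max_habitat`, to one decimal (half away
#' from zero). Negative margins are meaningful - they indicate that habitat
#' maxima already overlap the tolerance limit - and are returned as-is.
#'
#' @param ctmax Critical thermal maximum, degC (mean or individual).
#' @param t_max_habitat Maximum habitat water temperature over the sampling
#'   period, degC. Vectorised with `ctmax`.
#' @return Margin(s) in degC, one decimal.
#' @examples
#' safety_margin(41.4, 35.0) # 6.4
#' safety_margin(39.2, 28.95) # 10.3
#' @export
safety_margin <- function(ctmax, t_max_habitat) {
  stopifnot(is.numeric(ctmax), is.numeric(t_max_habitat))
  if (any(!is.finite(ctmax)) || any(!is.finite(t_max_habitat))) {
    abort("Safety margins need finite temperatures.", class = "thermotol_error_margin")
  }
  round_half_out(ctmax - t_max_habitat, 1L)
}

# Round half away from zero (so 11.45 -> 11.5), unlike base round()'s
# round-half-even. The 1e-8 guard absorbs binary representation error in
# differences like 40.4 - 28.95.
round_half_out <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}
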