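#' Recognised well roles in a plate table
#'
#' @format Character vector of the role vocabulary accepted by
#'   [read_plate_table()].
#' @export
plate_roles <- c(
  "treatment", "vehicle", "kill_control", "asymptote_control",
  "donor_only", "blank"
)

conc_unit_factor <- function(unit) {
  switch(unit,
    M  = 1,
    mM = 1e-3,
    uM = 1e-6,
    nM = 1e-9,
    abort(sprintf("Unknown concentration unit '%s' (use M, mM, uM or nM).", unit))
  )
}

#' Read and validate a long-format plate-reader table
#'
#' Reads a tidy CSV with one row per well, validates the schema, and converts
#' concentrations to molar. Required columns are `well`, `compound`, `conc`,
#' `role` and `signal`; `channel`, `time_h`, `replicate` and `conc_unit` are
#' optional (a `conc_unit` column overrides the `conc_unit` argument row-wise).
#'
#' Validation enforces: roles drawn from [plate_roles]; finite, non-negative
#' signals; strictly positive concentrations on treatment wells. Offending
#' rows are named in the error.
#'
#' @param path Path to a CSV file (or anything [readr::read_csv()] accepts).
#' @param conc_unit Unit of the `conc` column: `"M"`, `"mM"`, `"uM"` or `"nM"`.
#' @param config Optional list, or path to a YAML file, with elements
#'   `conc_unit` and/or `roles` (extra accepted role labels).
#' @return A tibble (class `plate_table`) with `conc` in molar.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(sim_dose_response(log10_ic50 = -5, cfg = sim_config(seed = 1)), path)
#' read_plate_table(path, conc_unit = "M")
read_plate_table <- function(path, conc_unit = "M", config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  conc_unit <- config$conc_unit %||% conc_unit
  roles <- unique(c(plate_roles, config$roles))

  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("well", "compound", "conc", "role", "signal")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Plate table is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!is.numeric(tbl$conc)) abort("Column 'conc' must be numeric.")
  if (!is.numeric(tbl$signal)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl$signal))))
    abort(sprintf("Column 'signal' must be numeric (first offending row: %d).",
                  if (length(bad)) bad[1] else 1L))
  }

  bad_role <- which(!tbl$role %in% roles)
  if (length(bad_role) > 0) {
    abort(sprintf("Unknown role '%s' in row %d (well %s).",
                  tbl$role[bad_role[1]], bad_role[1], tbl$well[bad_role[1]]))
  }
  bad_sig <- which(!is.finite(tbl$signal) | tbl$signal < 0)
  if (length(bad_sig) > 0) {
    abort(sprintf("Signal must be finite and non-negative (row %d, well %s).",
                  bad_sig[1], tbl$well[bad_sig[1]]))
  }

  fac <- if ("conc_unit" %in% names(tbl)) {
    vapply(tbl$conc_unit, conc_unit_factor, numeric(1))
  } else {
    conc_unit_factor(conc_unit)
  }
  tbl$conc <- tbl$conc * fac
  tbl$conc_unit <- NULL

  bad_trt <- which(tbl$role == "treatment" & !(tbl$conc > 0))
  if (length(bad_trt) > 0) {
    abort(sprintf("Treatment wells need concentration > 0 (row %d, well %s).",
                  bad_trt[1], tbl$well[bad_trt[1]]))
  }
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  class(tbl) <- c("plate_table", class(tbl))
  tbl
}

control_mean <- function(plate, which_role) {
  mean(plate$signal[plate$role == which_role])
}

#' Normalize raw signals to percent viability
#'
#' Rescales each well linearly between the vehicle-control mean (100%) and
#' the kill-control mean (0%): `100 * (signal - kill) / (vehicle - kill)`.
#' When no kill-control wells are present, a zero-signal floor anchors 0%.
#' Out-of-range percentages are retained so downstream fits see unbiased
#' data; replicates are averaged per compound and concentration after
#' normalization unless `average = FALSE`.
#'
#' @param plate A plate table (see [read_plate_table()]).
#' @param mode Output mode label, `"viability"` or `"sphere_formation"`.
#' @param average Average replicate wells per compound/concentration?
#' @return Tibble with columns `compound`, `conc`, `value`, `mode`.
#' @export
normalize_viability <- function(plate, mode = c("viability", "sphere_formation"),
                                average = TRUE) {
  mode <- match.arg(mode)
  if (!any(plate$role == "vehicle")) {
    abort("Viability normalization needs at least one vehicle well.")
  }
  veh <- control_mean(plate, "vehicle")
  kill <- if (any(plate$role == "kill_control")) {
    control_mean(plate, "kill_control")
  } else 0
  if (veh <= kill) {
    abort(sprintf(
      "Degenerate controls: vehicle mean (%.4g) must exceed kill mean (%.4g).",
      veh, kill))
  }
  out <- plate |>
    dplyr::filter(.data$role %in% c("treatment", "vehicle", "kill_control")) |>
    dplyr::mutate(value = 100 * (.data$signal - kill) / (veh - kill),
                  mode = mode) |>
    dplyr::select("compound", "conc", "value", "mode", "replicate")
  if (average) {
    out <- out |>
      dplyr::summarise(value = mean(.data$value),
                       .by = c("compound", "conc", "mode")) |>
      dplyr::select("compound", "conc", "value", "mode")
  }
  tibble::as_tibble(out)
}

#' Convert viability-type responses to percent inhibition (and back)
#'
#' `value' = 100 - value`; applying the complement to an inhibition table
#' restores viability, so the transform is an involution on the percent
#' scale.
#'
#' @param resp Tibble of normalized responses with columns `value`, `mode`.
#' @return The same tibble with complemented `value` and flipped `mode`.
#' @export
percent_inhibition <- function(resp) {
  flip <- c(viability = "inhibition", sphere_formation = "inhibition",
            inhibition = "viability", toxicity = "toxicity")
  if (!all(resp$mode %in% names(flip)) || any(resp$mode == "toxicity")) {
    abort("percent_inhibition() expects mode viability, sphere_formation or inhibition.")
  }
  dplyr::mutate(resp, value = 100 - .data$value,
                mode = unname(flip[.data$mode]))
}

#' Normalize raw signals to percent toxicity
#'
#' Vehicle wells anchor 0% toxicity. When max-lysis (`kill_control`) wells are
#' present they anchor 100%; otherwise the baseline-subtracted signal is
#' rescaled by the plate maximum, so the most affected well reads 100%.
#'
#' @inheritParams normalize_viability
#' @return Tibble with columns `compound`, `conc`, `value`, `mode = "toxicity"`.
#' @export
normalize_toxicity <- function(plate, average = TRUE) {
  if (!any(plate$role == "vehicle")) {
    abort("Toxicity normalization needs at least one vehicle well.")
  }
  veh <- control_mean(plate, "vehicle")
  top <- if (any(plate$role == "kill_control")) {
    control_mean(plate, "kill_control")
  } else {
    max(plate$signal[plate$role %in% c("treatment", "vehicle")])
  }
  if (top <= veh) {
    abort(sprintf(
      "Degenerate controls: max-signal anchor (%.4g) must exceed vehicle mean (%.4g).",
      top, veh))
  }
  out <- plate |>
    dplyr::filter(.data$role %in% c("treatment", "vehicle", "kill_control")) |>
    dplyr::mutate(value = 100 * (.data$signal - veh) / (top - veh),
                  mode = "toxicity") |>
    dplyr::select("compound", "conc", "value", "mode", "replicate")
  if (average) {
    out <- out |>
      dplyr::summarise(value = mean(.data$value),
                       .by = c("compound", "conc", "mode")) |>
      dplyr::select("compound", "conc", "value", "mode")
  }
  tibble::as_tibble(out)
}
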