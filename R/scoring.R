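#' Composite drug activity score
#'
#' Combines the phenotypic, selectivity, toxicity, and affinity readouts of
#' a screen into a single ranking quantity:
#'
#'   `score = dss_target^2 / dss_offtarget * tox_offtarget / tox_target / kd_uM`
#'
#' rewarding strong on-target spheroid activity (entering squared), on- vs
#' off-target cell-line selectivity, low relative toxicity in the off-target
#' line, and high target affinity. Kd enters in micromolar, so score
#' magnitudes are dimensionally heterogeneous by construction
#' (percent^2 per micromolar scale). Compounds with a non-positive
#' denominator are excluded with the reason recorded, not dropped silently.
#'
#' @param data Data frame with columns `compound`, `dss_target`,
#'   `dss_offtarget` (DSS3 in the target/off-target cell line),
#'   `tox_offtarget`, `tox_target` (percent 2D toxicity at the screening
#'   dose), and `kd_uM` (micromolar). An optional `series` column is carried
#'   through for per-series ranking.
#' @return The input tibble with `score`, `excluded`, `exclude_reason`
#'   columns added; excluded compounds have `score = NA`.
#' @export
#' @examples
#' composite_score(tibble::tibble(
#'   compound = "1", dss_target = 20, dss_offtarget = 10,
#'   tox_offtarget = 5, tox_target = 10, kd_uM = 0.87))
composite_score <- function(data) {
  req <- c("compound", "dss_target", "dss_offtarget", "tox_offtarget",
           "tox_target", "kd_uM")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    abort(sprintf("composite_score() needs column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  data |>
    dplyr::mutate(
      exclude_reason = dplyr::case_when(
        !(.data$dss_offtarget > 0) ~ "off-target DSS3 not positive",
        !(.data$tox_target > 0) ~ "target-line toxicity not positive",
        !(.data$kd_uM > 0) ~ "Kd not positive",
        .default = NA_character_),
      excluded = !is.na(.data$exclude_reason),
      score = dplyr::if_else(
        .data$excluded, NA_real_,
        .data$dss_target^2 / .data$dss_offtarget *
          .data$tox_offtarget / .data$tox_target / .data$kd_uM)) |>
    tibble::as_tibble()
}

#' Rank scored compounds and select the top of each series
#'
#' Orders by descending composite score, breaking ties by lower Kd and then
#' lexicographic compound id. When a `series` column is present the top
#' `top_n` compounds of each chemical series are retained.
#'
#' @param scores Output of [composite_score()].
#' @param top_n Compounds kept per series (default 3); `Inf` keeps all.
#' @return Ordered tibble of selected compounds with a `rank` column
#'   (overall rank among non-excluded compounds).
#' @export
rank_compounds <- function(scores, top_n = 3) {
  if (!any(!scores$excluded)) abort("No scorable compounds to rank.")
  ranked <- scores |>
    dplyr::filter(!.data$excluded) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$kd_uM, .data$compound) |>
    dplyr::mutate(rank = dplyr::row_number())
  if ("series" %in% names(ranked) && is.finite(top_n)) {
    ranked <- ranked |>
      dplyr::slice_min(.data$rank, n = top_n, by = "series") |>
      dplyr::arrange(.data$rank)
  }
  ranked
}
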