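# BRET donor-saturation analysis. The acceptor-channel (515 nm) to
# donor-channel (410 nm) emission ratio, background-corrected by donor-only
# cells, rises with acceptor/donor relative expression along a binding
# saturation curve y = BRETmax * x / (BRET50 + x).

#' Background-corrected BRET ratio
#'
#' Raw ratio = emission at 515 nm / emission at 410 nm; the donor-only raw
#' ratio (luciferase bleed-through into the acceptor channel) is subtracted:
#' `ratio = (515/410)_sample - (515/410)_donor_only`. Invariant under common
#' scaling of a well's two channels.
#'
#' @param em515,em410 Sample acceptor- and donor-channel emissions.
#' @param ref515,ref410 Donor-only reference emissions.
#' @return Dimensionless background-corrected ratio, vectorized.
#' @export
bret_ratio <- function(em515, em410, ref515, ref410) {
  if (any(em410 <= 0) || any(ref410 <= 0)) {
    abort("Donor-channel (410 nm) emission must be positive.")
  }
  em515 / em410 - ref515 / ref410
}

#' Acceptor expression relative to donor
#'
#' `RFU / RLU`: acceptor fluorescence over donor luminescence, proportional
#' to \[acceptor\]/\[donor\].
#'
#' @param rfu Acceptor fluorescence intensity.
#' @param rlu Donor luminescence (410 nm channel).
#' @return Dimensionless relative expression, vectorized.
#' @export
relative_expression <- function(rfu, rlu) {
  if (any(rlu <= 0)) abort("Donor luminescence must be positive.")
  rfu / rlu
}

#' Fit the BRET donor-saturation curve
#'
#' Least squares of `y = BRETmax * x / (BRET50 + x)` on a titration of
#' BRET ratio vs relative acceptor expression (technical replicates should
#' be pre-averaged; biological repeats may be pooled). When the data show
#' no curvature (fitted BRET50 far beyond the probed range) the asymptote
#' is unresolved and the initial slope is reported instead.
#'
#' @param data Data frame of the titration.
#' @param x,y Columns with relative expression and BRET ratio.
#' @return Object of class `saturation_fit`: `bret_max`, `bret_50`, `se`,
#'   `slope` (initial slope `bret_max/bret_50`), `rss`, `converged`,
#'   `saturating`, `n`, `data`.
#' @export
fit_saturation <- function(data, x = rel_expr, y = ratio) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) < 5) abort("A saturation fit needs at least 5 points.")
  pts <- tibble::tibble(x = xv, y = yv)
  se0 <- c(bret_max = NA_real_, bret_50 = NA_real_)
  lin <- lm(y ~ x - 1, data = pts)
  res <- function(bmax, b50, se, rss, converged, saturating) {
    structure(list(bret_max = bmax, bret_50 = b50, se = se,
                   slope = if (saturating) bmax / b50 else
                     unname(coef(lin)[["x"]]),
                   rss = rss, converged = converged, saturating = saturating,
                   n = nrow(pts), data = pts), class = "saturation_fit")
  }
  half <- xv[which.min(abs(yv - max(yv) / 2))]
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ bret_max * x / (bret_50 + x), data = pts,
      start = list(bret_max = max(yv) * 1.2, bret_50 = max(half, 1e-6)),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("Saturation fit did not converge; reporting initial slope only.")
    return(res(NA_real_, NA_real_, se0, NA_real_, FALSE, saturating = FALSE))
  }
  p <- coef(fit)
  if (p[["bret_50"]] > 50 * max(xv)) {
    warn("BRET ratio is linear in relative expression over the probed range; BRETmax/BRET50 unresolved.")
    return(res(NA_real_, NA_real_, se0, sum(resid(fit)^2), TRUE,
               saturating = FALSE))
  }
  se <- tryCatch(sqrt(diag(vcov(fit)))[c("bret_max", "bret_50")],
                 error = function(e) se0)
  res(unname(p[["bret_max"]]), unname(p[["bret_50"]]), se,
      sum(resid(fit)^2), TRUE, saturating = TRUE)
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (x$saturating) {
    cat(sprintf("<saturation_fit> BRETmax %.3g, BRET50 %.3g (n = %d)\n",
                x$bret_max, x$bret_50, x$n))
  } else {
    cat(sprintf("<saturation_fit> linear regime: slope %.3g (n = %d)\n",
                x$slope, x$n))
  }
  invisible(x)
}

#' Select the assay A/D plasmid ratio from a donor-saturation titration
#'
#' Picks the acceptor/donor plasmid ratio whose mean relative expression is
#' closest to `BRET50 / 2`, the sub-saturation region where the BRET ratio
#' still changes most linearly with expression while keeping a measurable
#' signal. Ties break toward the lower plasmid ratio. If every tested ratio
#' sits beyond saturation (mean expression > 3 BRET50), the ratio with the
#' lowest expression is returned with a warning.
#'
#' @param titration Data frame with columns `ad_ratio` and `rel_expr`
#'   (per-well or pre-averaged).
#' @param fit A saturating [fit_saturation()] result.
#' @return The selected `ad_ratio` value.
#' @export
select_assay_ad_ratio <- function(titration, fit) {
  stopifnot(inherits(fit, "saturation_fit"))
  if (!fit$saturating) abort("Assay-window selection needs a saturating fit.")
  means <- titration |>
    dplyr::summarise(mx = mean(.data$rel_expr), .by = "ad_ratio") |>
    dplyr::arrange(.data$ad_ratio)
  if (nrow(means) < 3) abort("Need at least 3 distinct A/D ratios.")
  target <- fit$bret_50 / 2
  if (all(means$mx > 3 * fit$bret_50)) {
    warn("All tested A/D ratios lie beyond saturation; returning the lowest-expression ratio.")
    return(means$ad_ratio[which.min(means$mx)])
  }
  d <- abs(means$mx - target)
  # ties break to the lower plasmid ratio (means is sorted ascending)
  means$ad_ratio[which(d <= min(d) + 1e-12)][1]
}

#' Convert treated BRET ratios to percent inhibition
#'
#' `inhibition_i = 100 (vehicle - treated_i) / vehicle`. An asymptote
#' reference treatment (e.g. a prenylation blocker giving maximal loss of
#' nanoclustering) defines the top asymptote `a` used when these traces are
#' scored with [dss()].
#'
#' @param treated Data frame with columns `treatment` and `ratio`
#'   (background-corrected BRET ratios); an optional `conc` column is
#'   carried through.
#' @param vehicle_ratio Vehicle-control BRET ratio (> 0).
#' @param asymptote_ratio Optional BRET ratio of the maximal-inhibition
#'   reference.
#' @return Tibble with `treatment`, (`conc`,) `value`, `mode = "inhibition"`;
#'   the asymptote `a` (percent) is attached as attribute `"a"` when a
#'   reference is supplied.
#' @export
bret_inhibition <- function(treated, vehicle_ratio, asymptote_ratio = NULL) {
  if (vehicle_ratio <= 0) abort("Vehicle BRET ratio must be positive.")
  out <- treated |>
    dplyr::mutate(value = 100 * (vehicle_ratio - .data$ratio) / vehicle_ratio,
                  mode = "inhibition") |>
    dplyr::select(dplyr::any_of(c("treatment", "conc")), "value", "mode") |>
    tibble::as_tibble()
  if (!is.null(asymptote_ratio)) {
    attr(out, "a") <- 100 * (vehicle_ratio - asymptote_ratio) / vehicle_ratio
  }
  out
}
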