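# Two-step covalent inhibition: E + I <-> E.I (Ki) -> E-I (k2, irreversible).
# Under pseudo-first-order conditions the FP signal decays exponentially with
# observed rate kobs = k2 [I] / (Ki + [I]); the hyperbola in [I] yields Ki
# and k2, and k2/Ki is the second-order engagement rate.

#' Fit a one-phase exponential decay to an FP time course
#'
#' Least squares of `y(t) = plateau + span * exp(-kobs * t)` with `kobs >= 0`
#' and an unconstrained plateau. A flat trace returns `kobs = 0` with a
#' low-confidence flag instead of failing.
#'
#' @param data Data frame of one time course at one inhibitor concentration.
#' @param time,signal Columns with time (hours) and signal (anisotropy or
#'   polarization units).
#' @return Object of class `kobs_fit`: `kobs` (per hour), `span`, `plateau`,
#'   `se`, `rss`, `converged`, `flat`, `n`, `data`.
#' @export
fit_kobs <- function(data, time = time_h, signal = signal) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ signal }})
  ord <- order(t); t <- t[ord]; y <- y[ord]
  if (length(t) < 4) abort("A time course needs at least 4 samples.")
  if (any(diff(t) <= 0)) abort("Time points must be strictly increasing.")
  pts <- tibble::tibble(time_h = t, signal = y)

  out <- function(kobs, span, plateau, se, rss, converged, flat) {
    structure(list(kobs = kobs, span = span, plateau = plateau, se = se,
                   rss = rss, converged = converged, flat = flat,
                   n = length(t), data = pts), class = "kobs_fit")
  }
  se0 <- c(kobs = NA_real_, span = NA_real_, plateau = NA_real_)
  rng <- diff(range(y))
  if (rng <= 1e-12 * max(abs(y), 1)) {
    return(out(0, 0, mean(y), se0, 0, TRUE, flat = TRUE))
  }

  # rate start from the half-life of the baseline-subtracted trace
  span0 <- y[1] - y[length(y)]
  plateau0 <- y[length(y)]
  half <- t[which.min(abs((y - plateau0) - span0 / 2))]
  k0 <- if (half > 0) log(2) / half else 1 / max(t)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      signal ~ plateau + span * exp(-kobs * time_h), data = pts,
      start = list(plateau = plateau0, span = span0, kobs = k0),
      lower = c(-Inf, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) return(out(NA_real_, NA_real_, NA_real_, se0, NA_real_,
                               FALSE, flat = FALSE))
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[c("kobs", "span", "plateau")],
                 error = function(e) se0)
  out(unname(p[["kobs"]]), unname(p[["span"]]), unname(p[["plateau"]]),
      se, sum(resid(fit)^2), TRUE,
      flat = abs(p[["span"]]) <= 1e-9 * max(abs(y), 1))
}

#' @export
print.kobs_fit <- function(x, ...) {
  cat(sprintf("<kobs_fit> kobs %.4g /h, span %.4g, plateau %.4g%s\n",
              x$kobs, x$span, x$plateau,
              if (isTRUE(x$flat)) " [flat trace]" else ""))
  invisible(x)
}

#' Fit the covalent-inhibition hyperbola kobs = k2 [I] / (Ki + [I])
#'
#' Global fit of per-concentration observed rates to the two-step covalent
#' model, yielding the non-covalent dissociation constant `Ki`, the maximal
#' bond-formation rate `k2`, and the second-order rate constant `k2/Ki`.
#' Points are weighted by inverse variance when a `kobs_se` column is
#' supplied. When no saturation is detectable (the fit runs into a Ki far
#' beyond the probed range, i.e. kobs is linear in \[I\]), only the
#' second-order constant is reported, from the origin-constrained slope,
#' with `Ki` and `k2` flagged unresolved.
#'
#' @param data Data frame with one row per inhibitor concentration.
#' @param conc,kobs Columns with concentration (molar) and observed rate
#'   (per hour).
#' @param kobs_se Optional column of standard errors on `kobs`.
#' @return Object of class `covalent_fit`: `ki` (molar), `k2` (per hour),
#'   `second_order` (per molar per hour), `se`, `rss`, `converged`,
#'   `saturating`, `n`, `data`.
#' @export
fit_ki_k2 <- function(data, conc = conc, kobs = kobs, kobs_se = NULL) {
  ci <- dplyr::pull(data, {{ conc }})
  ko <- dplyr::pull(data, {{ kobs }})
  se_q <- enquo(kobs_se)
  w <- if (!rlang::quo_is_null(se_q)) {
    s <- dplyr::pull(data, !!se_q)
    ifelse(is.finite(s) & s > 0, 1 / s^2, NA_real_)
  } else rep(1, length(ko))
  if (any(!is.finite(w))) w <- rep(1, length(ko))   # fall back to unweighted
  if (length(unique(ci)) < 3) {
    warn("Fewer than 3 concentrations: Ki/k2 poorly constrained.")
  }
  pts <- tibble::tibble(conc = ci, kobs = ko, w = w)

  lin <- lm(kobs ~ conc - 1, data = pts, weights = w)
  res <- function(ki, k2, se, rss, converged, saturating) {
    structure(list(ki = ki, k2 = k2,
                   second_order = if (saturating) k2 / ki else
                     unname(coef(lin)[["conc"]]),
                   se = se, rss = rss, converged = converged,
                   saturating = saturating, n = nrow(pts), data = pts,
                   fits = NULL), class = "covalent_fit")
  }
  se0 <- c(ki = NA_real_, k2 = NA_real_)

  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      kobs ~ k2 * conc / (ki + conc), data = pts, weights = w,
      start = list(k2 = max(ko) * 1.2, ki = stats::median(ci)),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("Hyperbolic fit did not converge; reporting slope-only second-order rate.")
    return(res(NA_real_, NA_real_, se0, NA_real_, FALSE, saturating = FALSE))
  }
  p <- coef(fit)
  if (p[["ki"]] > 50 * max(ci)) {
    warn("No saturation detectable over the probed range; Ki and k2 unresolved, second-order rate taken from the linear slope.")
    return(res(NA_real_, NA_real_, se0, sum(resid(fit)^2), TRUE,
               saturating = FALSE))
  }
  if (max(ci) < p[["ki"]]) {
    warn("Concentration series does not span the apparent Ki; estimates may be unstable.")
  }
  se <- tryCatch(sqrt(diag(vcov(fit)))[c("ki", "k2")], error = function(e) se0)
  res(unname(p[["ki"]]), unname(p[["k2"]]), se, sum(resid(fit)^2), TRUE,
      saturating = TRUE)
}

#' @export
print.covalent_fit <- function(x, ...) {
  if (x$saturating) {
    cat(sprintf(
      "<covalent_fit> Ki %.3g M, k2 %.3g /h, k2/Ki %.3g /M/h (n = %d)\n",
      x$ki, x$k2, x$second_order, x$n))
  } else {
    cat(sprintf(
      "<covalent_fit> linear regime: k2/Ki %.3g /M/h; Ki, k2 unresolved (n = %d)\n",
      x$second_order, x$n))
  }
  invisible(x)
}

#' Full covalent-kinetics pipeline from FP time courses
#'
#' Fits a one-phase decay per inhibitor concentration ([fit_kobs()]), then
#' the kobs hyperbola across concentrations ([fit_ki_k2()]), propagating
#' the per-concentration standard errors as weights.
#'
#' @param data Long data frame of FP time courses.
#' @param conc,time,signal Columns with inhibitor concentration (molar),
#'   time (hours), and FP signal.
#' @return A `covalent_fit` whose `fits` element holds the tidied
#'   per-concentration kobs table.
#' @export
covalent_kinetics <- function(data, conc = conc, time = time_h,
                              signal = signal) {
  per_conc <- data |>
    dplyr::group_by({{ conc }}) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::rename(conc = 1)
  kfits <- purrr::map(per_conc$data,
                      \(d) fit_kobs(d, time = {{ time }}, signal = {{ signal }}))
  ktab <- tibble::tibble(
    conc = per_conc$conc,
    kobs = purrr::map_dbl(kfits, "kobs"),
    kobs_se = purrr::map_dbl(kfits, \(f) unname(f$se[["kobs"]])),
    flat = purrr::map_lgl(kfits, "flat"),
    converged = purrr::map_lgl(kfits, "converged"))
  fit <- fit_ki_k2(ktab, conc = conc, kobs = kobs, kobs_se = kobs_se)
  fit$fits <- ktab
  fit
}

#' Second-order covalent engagement rate
#'
#' @param k2 Maximal covalent rate (per hour).
#' @param ki Non-covalent dissociation constant (molar).
#' @return `k2 / ki` in per molar per hour, vectorized.
#' @export
second_order_rate <- function(k2, ki) {
  stopifnot(all(ki > 0))
  k2 / ki
}

#' Round a second-order rate to tabulated precision
#'
#' Reporting convention for rates in the 10^3-10^5 /M/h range: 2 significant
#' figures at or above 10 x 10^3, 1 below, i.e. always one or two digits in
#' units of 10^3 /M/h.
#'
#' @param rate Second-order rate(s) in per molar per hour.
#' @return Rounded rate(s) on the same scale, vectorized.
#' @export
round_second_order <- function(rate) {
  ifelse(rate >= 10e3, signif(rate, 2), signif(rate, 1))
}
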