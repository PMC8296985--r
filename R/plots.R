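# ggplot2 autoplot methods for the fitted-object classes

#' Plot a fitted dose-response curve
#'
#' Points are the fitted observations on a log10-concentration axis; the
#' line is the fitted four-parameter logistic.
#'
#' @param object A `logistic4_fit`.
#' @param n Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.logistic4_fit <- function(object, n = 200, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 concentration (M)", y = "response")
  if (object$converged) {
    xs <- seq(min(object$data$x), max(object$data$x), length.out = n)
    curve <- tibble::tibble(
      x = xs, y = logistic4_value(xs, object$bottom, object$top,
                                  object$hill, object$log10_mid))
    p <- p + ggplot2::geom_line(data = curve)
  }
  p
}

#' Plot a one-phase decay fit
#'
#' @param object A `kobs_fit`.
#' @param n Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kobs_fit <- function(object, n = 200, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "FP signal")
  if (object$converged) {
    ts <- seq(min(object$data$time_h), max(object$data$time_h),
              length.out = n)
    curve <- tibble::tibble(
      time_h = ts, signal = object$plateau + object$span *
        exp(-object$kobs * ts))
    p <- p + ggplot2::geom_line(data = curve)
  }
  p
}

#' Plot the covalent kobs hyperbola
#'
#' Observed per-concentration rates with the fitted
#' `kobs = k2 [I] / (Ki + [I])` curve (or the origin-constrained line in
#' the non-saturating regime).
#'
#' @param object A `covalent_fit`.
#' @param n Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.covalent_fit <- function(object, n = 200, ...) {
  cs <- seq(0, max(object$data$conc), length.out = n)
  curve <- tibble::tibble(
    conc = cs,
    kobs = if (object$saturating) object$k2 * cs / (object$ki + cs)
           else object$second_order * cs)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$kobs)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "[inhibitor] (M)", y = "kobs (1/h)")
}

#' Plot a BRET donor-saturation fit
#'
#' @param object A `saturation_fit`.
#' @param n Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_fit <- function(object, n = 200, ...) {
  xs <- seq(0, max(object$data$x), length.out = n)
  curve <- tibble::tibble(
    x = xs,
    y = if (object$saturating) object$bret_max * xs / (object$bret_50 + xs)
        else object$slope * xs)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "relative expression ([acceptor]/[donor])",
                  y = "BRET ratio")
}
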