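# broom-style tidiers for the fitted-object classes

tidy_params <- function(est, se) {
  tibble::tibble(term = names(est), estimate = unname(unlist(est)),
                 std.error = unname(se[names(est)]))
}

#' @rdname fit_logistic4
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.logistic4_fit <- function(x, ...) {
  tidy_params(x[c("bottom", "top", "hill", "log10_mid")], x$se)
}

#' @rdname fit_logistic4
#' @export
glance.logistic4_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, rss = x$rss, n = x$n,
                 converged = x$converged, reason = x$reason)
}

#' @rdname fit_kobs
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.kobs_fit <- function(x, ...) {
  tidy_params(x[c("kobs", "span", "plateau")], x$se)
}

#' @rdname fit_kobs
#' @export
glance.kobs_fit <- function(x, ...) {
  tibble::tibble(kobs = x$kobs, rss = x$rss, n = x$n,
                 converged = x$converged, flat = x$flat)
}

#' @rdname fit_ki_k2
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.covalent_fit <- function(x, ...) {
  tidy_params(list(ki = x$ki, k2 = x$k2), x$se) |>
    dplyr::bind_rows(tibble::tibble(term = "second_order",
                                    estimate = x$second_order,
                                    std.error = NA_real_))
}

#' @rdname fit_ki_k2
#' @export
glance.covalent_fit <- function(x, ...) {
  tibble::tibble(ki = x$ki, k2 = x$k2, second_order = x$second_order,
                 rss = x$rss, n = x$n, converged = x$converged,
                 saturating = x$saturating)
}

#' @rdname fit_saturation
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  tidy_params(list(bret_max = x$bret_max, bret_50 = x$bret_50), x$se)
}

#' @rdname fit_saturation
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(bret_max = x$bret_max, bret_50 = x$bret_50,
                 slope = x$slope, rss = x$rss, n = x$n,
                 converged = x$converged, saturating = x$saturating)
}
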