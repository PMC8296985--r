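# Four-parameter log-logistic model, evaluated at x = log10(concentration/M):
#   y(x) = bottom + (top - bottom) / (1 + 10^(hill * (log10_mid - x)))
# hill > 0 gives a response rising with concentration; a falling curve is
# represented canonically with hill < 0 and top >= bottom.

#' Evaluate the four-parameter log-logistic curve
#'
#' @param x Log10 concentration (molar).
#' @param bottom,top,hill,log10_mid Curve parameters; `hill > 0` rises with
#'   concentration.
#' @return Response value(s).
#' @export
logistic4_value <- function(x, bottom, top, hill, log10_mid) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10_mid - x)))
}

# numerically safe softplus: log(1 + exp(z))
softplus <- function(z) ifelse(z > 30, z + log1p(exp(-z)), log1p(exp(z)))

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Bounded Levenberg-Marquardt least squares of
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10_mid - x)))` on
#' `x = log10(conc)`, with three deterministic midpoint starts. The fit is
#' canonicalized so `top >= bottom`, with the sign of `hill` carrying the
#' direction (positive = response increases with concentration). Failure to
#' converge yields an inconclusive fit object, not an error.
#'
#' @param data Data frame of dose-response observations.
#' @param conc,response Columns (tidy-eval) holding concentration in molar
#'   and the measured response.
#' @param bounds Optional named list of `c(lower, upper)` bounds for
#'   `bottom`, `top`, `hill`, `log10_mid`. The default percent-scale bounds
#'   are bottom \[-10, 50\], top \[0, 120\], |hill| \[0.2, 10\], log10_mid
#'   within the observed range +/- 2. Use `bounds = "free"` for data on an
#'   arbitrary signal scale (e.g. anisotropy), where bounds are derived from
#'   the data.
#' @param descending Allow/force a falling curve. `NA` (default) tries both
#'   orientations and keeps the better one.
#' @return An object of class `logistic4_fit` with elements `bottom`, `top`,
#'   `hill`, `log10_mid`, `ic50` (molar), `se`, `rss`, `converged`, `n`,
#'   `data`. `tidy()` and `glance()` methods are provided.
#' @export
#' @examples
#' d <- tibble::tibble(conc = 10^seq(-7, -3, length.out = 8),
#'                     response = logistic4_value(log10(conc), 0, 100, 1, -5))
#' fit_logistic4(d)
fit_logistic4 <- function(data, conc = conc, response = response,
                          bounds = NULL, descending = NA) {
  x <- log10(dplyr::pull(data, {{ conc }}))
  y <- dplyr::pull(data, {{ response }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  pts <- tibble::tibble(x = x, y = y)

  inconclusive <- function(reason) {
    structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                   log10_mid = NA_real_, ic50 = NA_real_,
                   se = c(bottom = NA, top = NA, hill = NA, log10_mid = NA),
                   rss = NA_real_, converged = FALSE, reason = reason,
                   n = nrow(pts), data = pts),
              class = "logistic4_fit")
  }
  if (length(unique(x)) < 4) return(inconclusive("fewer than 4 distinct concentrations"))
  if (sd(y) == 0) return(inconclusive("flat response"))

  free <- identical(bounds, "free")
  span <- diff(range(y))
  b <- list(bottom = c(-10, 50), top = c(0, 120), hill = c(0.2, 10),
            log10_mid = c(min(x) - 2, max(x) + 2))
  if (free) {
    pad <- 0.5 * max(span, 1e-12)
    b$bottom <- c(min(y) - pad, max(y) + pad)
    b$top <- b$bottom
  }
  if (is.list(bounds)) b[names(bounds)] <- bounds

  fit_one <- function(desc, m0) {
    # with hill < 0 the top asymptote sits at low dose, so top >= bottom in
    # both orientations and only the hill sign differs between starts
    start <- list(bottom = min(max(min(y), b$bottom[1]), b$bottom[2]),
                  top = min(max(max(y), b$top[1]), b$top[2]),
                  hill = if (desc) -1 else 1, log10_mid = m0)
    lower <- c(b$bottom[1], b$top[1], if (desc) -b$hill[2] else b$hill[1], b$log10_mid[1])
    upper <- c(b$bottom[2], b$top[2], if (desc) -b$hill[1] else b$hill[2], b$log10_mid[2])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (log10_mid - x))),
        data = pts, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) NULL)
    fit
  }

  # midpoint starts inside the window plus one either side, for curves whose
  # transition lies outside the screened range
  mids <- c(unname(quantile(x, c(0.25, 0.5, 0.75))),
            min(x) - 1.5, max(x) + 1.5)
  desc_opts <- if (is.na(descending)) c(FALSE, TRUE) else descending
  fits <- list()
  for (d in desc_opts) for (m0 in mids) {
    f <- fit_one(d, m0)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (length(fits) == 0) return(inconclusive("nonlinear least squares did not converge"))
  rssv <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  best <- fits[[which.min(rssv)]]

  p <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e)
    setNames(rep(NA_real_, 4), names(p)))
  # canonical orientation: top >= bottom
  if (p[["top"]] < p[["bottom"]]) {
    p[c("bottom", "top")] <- p[c("top", "bottom")]
    se[c("bottom", "top")] <- se[c("top", "bottom")]
    p[["hill"]] <- -p[["hill"]]
  }
  structure(list(bottom = unname(p[["bottom"]]), top = unname(p[["top"]]),
                 hill = unname(p[["hill"]]), log10_mid = unname(p[["log10_mid"]]),
                 ic50 = 10^unname(p[["log10_mid"]]),
                 se = se[c("bottom", "top", "hill", "log10_mid")],
                 rss = min(rssv), converged = TRUE, reason = NA_character_,
                 n = nrow(pts), data = pts),
            class = "logistic4_fit")
}

#' @export
print.logistic4_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<logistic4_fit> inconclusive:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<logistic4_fit> bottom %.3g, top %.3g, hill %.3g, logIC50 %.3g (IC50 %.3g M), n = %d\n",
    x$bottom, x$top, x$hill, x$log10_mid, x$ic50, x$n))
  invisible(x)
}

#' Closed-form area under a fitted log-logistic curve
#'
#' Exact integral of the four-parameter logistic over a log10-concentration
#' window. Writing k = hill * ln(10), the antiderivative of
#' `1 / (1 + 10^(hill (m - x)))` is `softplus(k (x - m)) / k`, so
#' `AUC = bottom (hi - lo) + (top - bottom) / k *
#'        [softplus(k (hi - m)) - softplus(k (lo - m))]`.
#'
#' @param fit A `logistic4_fit`, or a named list with `bottom`, `top`,
#'   `hill`, `log10_mid`.
#' @param lo,hi Integration bounds in log10 molar, `lo <= hi`.
#' @return Area in percent x log10-molar units.
#' @export
auc_logistic4 <- function(fit, lo, hi) {
  stopifnot(lo <= hi)
  k <- fit$hill * log(10)
  if (abs(k) < 1e-14) {
    return((fit$bottom + (fit$top - fit$bottom) / 2) * (hi - lo))
  }
  fit$bottom * (hi - lo) + (fit$top - fit$bottom) / k *
    (softplus(k * (hi - fit$log10_mid)) - softplus(k * (lo - fit$log10_mid)))
}

# log-concentration at which the rising canonical curve crosses `level`;
# NA when the curve never reaches it
logistic4_invert <- function(fit, level) {
  lo <- min(fit$bottom, fit$top); hi <- max(fit$bottom, fit$top)
  if (level <= lo || level >= hi) return(NA_real_)
  fit$log10_mid -
    log10((fit$top - fit$bottom) / (level - fit$bottom) - 1) / fit$hill
}

#' Drug sensitivity scores (DSS1, DSS2, DSS3) from a dose-response fit
#'
#' Normalized area-under-curve summaries of a percent-inhibition
#' dose-response curve over the screened window
#' `[cmin, cmax]` (log10 molar). With `x2 = cmax`, `x1` the log-concentration
#' where the fitted response first reaches the activity threshold `t`
#' (clamped to the window), and AUC the exact integral of the fitted curve
#' on `[x1, x2]`:
#'
#'   DSS1 = (AUC - t (x2 - x1)) / ((100 - t) (cmax - cmin))
#'   DSS2 = DSS1 / log10(a)
#'   DSS3 = DSS2 (x2 - x1) / (cmax - cmin)
#'
#' where `a` is the top asymptote (percent), clamped to `[t, 100]` before
#' the log. Scores are reported on a 0-100 scale (the raw expressions above
#' live on 0-1) and floored at 0. A curve that never exceeds `t` on the
#' window scores 0. DSS3 emphasises compounds whose response spans a wide
#' dose window rather than appearing only at the top dose.
#'
#' @param fit A converged `logistic4_fit` of percent inhibition vs molar
#'   concentration.
#' @param t Minimal activity threshold in percent (default 10).
#' @param cmin,cmax Log10 of the lowest/highest screened concentration
#'   (molar). E.g. a 0.6-40 uM screen has `cmin = log10(0.6e-6)`.
#' @param compound Optional compound label carried into the result.
#' @param a Optional externally measured top asymptote in percent (e.g. the
#'   maximal inhibition of a reference treatment in a BRET assay); defaults
#'   to the fitted top.
#' @return One-row tibble: `compound`, `dss1`, `dss2`, `dss3`, `auc`, `t`,
#'   `a`, `x1`, `x2`, `cmin`, `cmax`, `ic50`, `inconclusive`.
#' @export
dss <- function(fit, t = 10, cmin, cmax, compound = NA_character_, a = NULL) {
  stopifnot(cmin < cmax)
  zero <- function(inconc = FALSE) tibble::tibble(
    compound = compound, dss1 = 0, dss2 = 0, dss3 = 0, auc = NA_real_,
    t = t, a = NA_real_, x1 = NA_real_, x2 = cmax, cmin = cmin, cmax = cmax,
    ic50 = if (inherits(fit, "logistic4_fit")) fit$ic50 else NA_real_,
    inconclusive = inconc)
  if (inherits(fit, "logistic4_fit") && !fit$converged) return(zero(TRUE))

  f <- fit[c("bottom", "top", "hill", "log10_mid")]
  y_cmin <- logistic4_value(cmin, f$bottom, f$top, f$hill, f$log10_mid)
  y_cmax <- logistic4_value(cmax, f$bottom, f$top, f$hill, f$log10_mid)
  # inhibition must not fall with dose (an effectively flat curve is fine)
  if (y_cmax < y_cmin - 1e-6 * max(abs(y_cmin), 1)) return(zero(TRUE))
  a <- min(max(a %||% f$top, t), 100)
  if (a <= 1) {
    warn("Top asymptote <= 1% after clamping; DSS set to 0.")
    return(zero())
  }
  if (max(y_cmin, y_cmax) < t) return(zero())

  x1 <- if (y_cmin >= t) cmin else logistic4_invert(f, t)
  if (is.na(x1)) return(zero())
  x1 <- min(max(x1, cmin), cmax)
  x2 <- cmax

  auc <- auc_logistic4(f, x1, x2)
  width <- cmax - cmin
  dss1 <- (auc - t * (x2 - x1)) / ((100 - t) * width)
  dss1 <- max(dss1, 0)
  dss2 <- dss1 / log10(a)
  dss3 <- dss2 * (x2 - x1) / width
  tibble::tibble(
    compound = compound, dss1 = 100 * dss1, dss2 = 100 * dss2,
    dss3 = 100 * dss3, auc = auc, t = t, a = a, x1 = x1, x2 = x2,
    cmin = cmin, cmax = cmax,
    ic50 = if (inherits(fit, "logistic4_fit")) fit$ic50 else 10^f$log10_mid,
    inconclusive = FALSE)
}

#' Selectivity ratio of two DSS results
#'
#' Ratio of DSS3 scores, e.g. KRAS-mutant over HRAS-mutant cell line, used
#' to annotate compound selectivity.
#'
#' @param a,b One-row DSS tibbles (see [dss()]); the ratio is `a$dss3 / b$dss3`.
#' @return A single number, or `NA` with a warning when `b$dss3` is 0.
#' @export
selectivity_ratio <- function(a, b) {
  if (b$dss3 <= 0) {
    warn("Denominator DSS3 is 0; selectivity ratio undefined.")
    return(NA_real_)
  }
  a$dss3 / b$dss3
}
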