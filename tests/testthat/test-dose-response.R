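test_that("noiseless four-parameter curves are recovered to high precision", {
  cases <- list(c(0, 100, 1, -5), c(5, 85, 2.3, -5.5), c(0, 60, 0.7, -4.6))
  for (p in cases) {
    d <- tibble::tibble(conc = 10^seq(-7.5, -3, length.out = 10),
                        response = logistic4_value(log10(conc), p[1], p[2],
                                                   p[3], p[4]))
    f <- fit_logistic4(d)
    expect_true(f$converged)
    expect_equal(c(f$bottom, f$top, f$hill, f$log10_mid), p,
                 tolerance = 1e-6)
    expect_equal(f$ic50, 10^p[4], tolerance = 1e-6)
  }
})

test_that("logIC50 and molar IC50 are consistent at tabulated precision", {
  # a midpoint of log10(12e-6) must be reported as IC50 = 12 uM
  d <- tibble::tibble(conc = 10^seq(-7, -3, length.out = 10),
                      response = logistic4_value(log10(conc), 0, 100, 1.2,
                                                 log10(12e-6)))
  f <- fit_logistic4(d)
  expect_equal(f$ic50, 12e-6, tolerance = 1e-6)
  expect_equal(round(f$log10_mid, 2), -4.92)
})

test_that("the fitter agrees with a coarse grid-search oracle on noisy data", {
  set.seed(7)
  x <- seq(-7, -3.5, length.out = 12)
  y <- logistic4_value(x, 0, 90, 1.5, -5.2) + rnorm(12, sd = 3)
  g <- grid_fit_logistic4(x, y,
                          bottoms = seq(-10, 20, by = 5),
                          tops = seq(60, 120, by = 5),
                          hills = seq(0.5, 3, by = 0.25),
                          mids = seq(-6.5, -4, by = 0.1))
  f <- fit_logistic4(tibble::tibble(conc = 10^x, response = y))
  expect_true(f$converged)
  # LM must do at least as well as the grid, and land within grid resolution
  expect_lte(f$rss, g$rss + 1e-9)
  expect_equal(f$top, unname(g$par["top"]), tolerance = 0.1)
  expect_equal(f$log10_mid, unname(g$par["log10_mid"]), tolerance = 0.1)
})

test_that("degenerate inputs give an inconclusive fit, not an error", {
  flat <- tibble::tibble(conc = 10^seq(-7, -4, length.out = 6), response = 20)
  expect_false(fit_logistic4(flat)$converged)
  few <- tibble::tibble(conc = c(1e-6, 1e-5, 1e-4), response = c(1, 50, 99))
  expect_false(fit_logistic4(few)$converged)
  expect_equal(dss(fit_logistic4(flat), t = 10, cmin = -7, cmax = -4)$dss3, 0)
})

test_that("closed-form AUC matches constant curves and adaptive quadrature", {
  expect_equal(auc_logistic4(list(bottom = 0, top = 0, hill = 1,
                                  log10_mid = -5), -6, -4), 0)
  expect_equal(auc_logistic4(list(bottom = 100, top = 100, hill = 1,
                                  log10_mid = -5), -6, -4), 200)
  set.seed(11)
  for (i in 1:200) {
    fit <- list(bottom = runif(1, -10, 50), top = runif(1, 0, 120),
                hill = runif(1, 0.2, 10) * sample(c(-1, 1), 1),
                log10_mid = runif(1, -8, -3))
    lo <- runif(1, -9, -5); hi <- lo + runif(1, 0.1, 4)
    expect_equal(auc_logistic4(fit, lo, hi), auc_quad(fit, lo, hi),
                 tolerance = 1e-6)
  }
})

test_that("full inhibition scores DSS1 = 100, DSS2 = DSS3 = 50; no response scores 0", {
  full <- make_l4(100, 100, 1, -20)
  s <- dss(full, t = 10, cmin = -6, cmax = -4)
  expect_equal(s$dss1, 100, tolerance = 1e-9)
  expect_equal(s$dss2, 50, tolerance = 1e-9)
  expect_equal(s$dss3, 50, tolerance = 1e-9)

  none <- make_l4(0, 0, 1, 20)
  z <- dss(none, t = 10, cmin = -6, cmax = -4)
  expect_equal(c(z$dss1, z$dss2, z$dss3), c(0, 0, 0))
})

test_that("DSS matches the printed formulas evaluated by numeric integration", {
  cases <- list(
    make_l4(0, 80, 1, -5),       # midpoint at centre of range
    make_l4(0, 100, 2.5, -4.5),  # steep, shifted high
    make_l4(5, 95, 0.6, -5.8),   # shallow, shifted low
    make_l4(0, 40, 1, -5))       # weak asymptote
  for (fit in cases) {
    s <- dss(fit, t = 10, cmin = -6, cmax = -4)
    o <- dss_numeric(fit, t = 10, cmin = -6, cmax = -4)
    expect_equal(c(s$dss1, s$dss2, s$dss3), unname(o), tolerance = 1e-6)
  }
})

test_that("selectivity ratio divides DSS3 values and flags a zero denominator", {
  a <- dss(make_l4(0, 90, 1, -5), t = 10, cmin = -6, cmax = -4)
  expect_equal(selectivity_ratio(a, a), 1)
  b <- a; b$dss3 <- a$dss3 / 3
  expect_equal(selectivity_ratio(a, b), 3)
  z <- a; z$dss3 <- 0
  expect_warning(r <- selectivity_ratio(a, z), "undefined")
  expect_true(is.na(r))
})

test_that("DSS1 is monotone in the top asymptote", {
  tops <- seq(20, 100, by = 10)
  d1 <- vapply(tops, function(a)
    dss(make_l4(0, a, 1, -5), t = 10, cmin = -6, cmax = -4)$dss1, numeric(1))
  expect_true(all(diff(d1) >= -1e-12))
})

test_that("a response confined to the top of the range is down-weighted by DSS3", {
  narrow <- make_l4(0, 100, 6, -4.1)  # reaches t only near the top dose
  s <- dss(narrow, t = 10, cmin = -6, cmax = -4)
  expect_lt(s$dss3, 0.35 * s$dss1)
  expect_equal(s$dss3 / s$dss2, (s$x2 - s$x1) / (s$cmax - s$cmin))
})

test_that("DSS is equivariant under a common log-concentration shift", {
  fit <- make_l4(0, 85, 1.4, -5.2)
  s0 <- dss(fit, t = 10, cmin = -6.2, cmax = -4.1)
  shift <- 1.7
  fit2 <- make_l4(0, 85, 1.4, -5.2 + shift)
  s1 <- dss(fit2, t = 10, cmin = -6.2 + shift, cmax = -4.1 + shift)
  expect_equal(c(s0$dss1, s0$dss2, s0$dss3), c(s1$dss1, s1$dss2, s1$dss3),
               tolerance = 1e-9)
})

test_that("tidy and glance expose the fitted parameters", {
  d <- tibble::tibble(conc = 10^seq(-7, -3, length.out = 8),
                      response = logistic4_value(log10(conc), 0, 100, 1, -5))
  f <- fit_logistic4(d)
  td <- tidy(f)
  expect_equal(td$term, c("bottom", "top", "hill", "log10_mid"))
  expect_equal(td$estimate[2], 100, tolerance = 1e-6)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$ic50, 1e-5, tolerance = 1e-6)
})
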