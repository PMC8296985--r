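# Independent brute-force oracles used to audit the fitted routes.

# coarse grid search for the 4PL, independent of the LM fitter
grid_fit_logistic4 <- function(x, y, bottoms, tops, hills, mids) {
  best <- NULL; best_rss <- Inf
  for (b in bottoms) for (a in tops) for (h in hills) for (m in mids) {
    yy <- b + (a - b) / (1 + 10^(h * (m - x)))
    rss <- sum((y - yy)^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(bottom = b, top = a, hill = h, log10_mid = m) }
  }
  list(par = best, rss = best_rss)
}

# adaptive-quadrature AUC oracle
auc_quad <- function(fit, lo, hi) {
  integrate(function(x) logistic4_value(x, fit$bottom, fit$top, fit$hill,
                                        fit$log10_mid),
            lo, hi, rel.tol = 1e-10)$value
}

# competitive equilibrium by iteratively refined grid scan over free protein
eq_grid_scan <- function(config, I_t, kd, passes = 6, n = 2000) {
  lo <- 0; hi <- config$E_t
  bal <- function(E) {
    E * (1 + config$P_t / (config$KD_probe + E) + I_t / (kd + E)) - config$E_t
  }
  for (p in seq_len(passes)) {
    Es <- seq(lo, hi, length.out = n)
    i <- which.min(abs(bal(Es)))
    lo <- Es[max(i - 1, 1)]; hi <- Es[min(i + 1, n)]
  }
  E <- (lo + hi) / 2
  P <- config$P_t * config$KD_probe / (config$KD_probe + E)
  I <- I_t * kd / (kd + E)
  list(E_free = E, P_free = P, I_free = I, EP = E * P / config$KD_probe,
       EI = E * I / kd)
}

# grid search for the one-phase decay
grid_fit_decay <- function(t, y, plateaus, spans, ks) {
  best <- NULL; best_rss <- Inf
  for (p in plateaus) for (s in spans) for (k in ks) {
    rss <- sum((y - (p + s * exp(-k * t)))^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(plateau = p, span = s, kobs = k) }
  }
  best
}

# grid search for the binding saturation curve
grid_fit_saturation <- function(x, y, bmaxs, b50s) {
  best <- NULL; best_rss <- Inf
  for (bm in bmaxs) for (b5 in b50s) {
    rss <- sum((y - bm * x / (b5 + x))^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(bret_max = bm, bret_50 = b5) }
  }
  best
}

# DSS computed directly from the printed formulas with numeric integration,
# independent of auc_logistic4/dss internals
dss_numeric <- function(fit, t, cmin, cmax) {
  f <- function(x) logistic4_value(x, fit$bottom, fit$top, fit$hill,
                                   fit$log10_mid)
  if (max(f(cmin), f(cmax)) < t) return(c(dss1 = 0, dss2 = 0, dss3 = 0))
  x1 <- if (f(cmin) >= t) cmin else
    uniroot(function(x) f(x) - t, c(cmin, cmax), tol = 1e-12)$root
  x2 <- cmax
  auc <- integrate(f, x1, x2, rel.tol = 1e-10)$value
  a <- min(max(fit$top, t), 100)
  d1 <- max((auc - t * (x2 - x1)) / ((100 - t) * (cmax - cmin)), 0)
  d2 <- d1 / log10(a)
  d3 <- d2 * (x2 - x1) / (cmax - cmin)
  c(dss1 = 100 * d1, dss2 = 100 * d2, dss3 = 100 * d3)
}

# convenience: a converged logistic4_fit object from known parameters
make_l4 <- function(bottom, top, hill, log10_mid) {
  structure(list(bottom = bottom, top = top, hill = hill,
                 log10_mid = log10_mid, ic50 = 10^log10_mid,
                 se = c(bottom = NA, top = NA, hill = NA, log10_mid = NA),
                 rss = 0, converged = TRUE, reason = NA_character_, n = 0,
                 data = tibble::tibble(x = numeric(), y = numeric())),
            class = "logistic4_fit")
}
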