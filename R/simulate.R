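# Seeded generators emulating the statistical structure of each assay:
# raw dose-response plates with vehicle/kill controls, FP displacement
# titrations driven by the competitive equilibrium, covalent FP time
# courses, and BRET donor-saturation titrations. Noise is multiplicative
# (plate-reader CV) plus an additive floor; a fixed seed makes every
# generator bit-reproducible without touching the caller's RNG state.

#' Simulation configuration
#'
#' @param seed Integer seed; fixes every generated table bit-identically.
#' @param cv Multiplicative noise (coefficient of variation; default 2%,
#'   typical plate-reader well-to-well variation).
#' @param sd_add Additive noise floor in signal units (default 0).
#' @param replicates Technical replicates per condition.
#' @param conc Optional molar concentration series override.
#' @param times Optional time grid override (hours).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, cv = 0.02, sd_add = 0, replicates = 3L,
                       conc = NULL, times = NULL) {
  stopifnot(cv >= 0, sd_add >= 0, replicates >= 1)
  structure(list(seed = as.integer(seed), cv = cv, sd_add = sd_add,
                 replicates = as.integer(replicates), conc = conc,
                 times = times), class = "sim_config")
}

noisy <- function(x, cfg) {
  x * (1 + rnorm(length(x), sd = cfg$cv)) + rnorm(length(x), sd = cfg$sd_add)
}

#' Simulate a raw dose-response plate
#'
#' Generates well-level raw fluorescence for one compound plus vehicle and
#' kill-control wells, such that the normalized percent-inhibition responses
#' have expectation equal to the generating log-logistic curve. The raw
#' viability signal is `kill + (vehicle - kill) * (100 - inhibition) / 100`
#' before noise.
#'
#' @param bottom,top,hill,log10_ic50 True percent-inhibition curve
#'   parameters (see [logistic4_value()]).
#' @param cfg A [sim_config()]; `cfg$conc` defaults to a 0.6-40 uM
#'   half-log-style 10-point series.
#' @param compound Compound label.
#' @param vehicle_signal,kill_signal Mean raw signals of the control
#'   anchors.
#' @param n_controls Vehicle and kill wells each.
#' @return A plate-table tibble (`well`, `compound`, `conc`, `role`,
#'   `channel`, `signal`, `replicate`) with `conc` in molar.
#' @export
sim_dose_response <- function(bottom = 0, top = 100, hill = 1, log10_ic50,
                              cfg = sim_config(), compound = "cmpd",
                              vehicle_signal = 10000, kill_signal = 500,
                              n_controls = 4L) {
  conc <- cfg$conc %||% exp(seq(log(0.6e-6), log(40e-6), length.out = 10))
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(conc = conc, replicate = seq_len(cfg$replicates))
    inh <- logistic4_value(log10(grid$conc), bottom, top, hill, log10_ic50)
    mu <- kill_signal + (vehicle_signal - kill_signal) * (100 - inh) / 100
    trt <- tibble::tibble(
      well = sprintf("T%02d", seq_len(nrow(grid))), compound = compound,
      conc = grid$conc, role = "treatment", channel = "fi",
      signal = noisy(mu, cfg), replicate = grid$replicate)
    ctrl <- tibble::tibble(
      well = sprintf("C%02d", seq_len(2 * n_controls)),
      compound = rep(c("vehicle", "kill"), each = n_controls),
      conc = 0,
      role = rep(c("vehicle", "kill_control"), each = n_controls),
      channel = "fi",
      signal = noisy(rep(c(vehicle_signal, kill_signal), each = n_controls),
                     cfg),
      replicate = rep(seq_len(n_controls), 2))
    dplyr::bind_rows(trt, ctrl)
  })
}

#' Simulate an FP displacement titration
#'
#' Anisotropy generated from the competitive binding equilibrium:
#' `r = r_free + (r_bound - r_free) * EP / P_t`, with EP from
#' [solve_competitive_equilibrium()] at each total inhibitor concentration,
#' plus noise. The default series is a 12-step 3-fold dilution bracketing
#' the expected transition midpoint ([kd_to_ic50()]), the standard way a
#' displacement titration is designed.
#'
#' @param kd True inhibitor dissociation constant (molar).
#' @param config An [fp_config()].
#' @param cfg A [sim_config()].
#' @param r_free,r_bound Anisotropy of free and fully protein-bound probe.
#' @param compound Compound label.
#' @return Tibble `compound`, `conc`, `replicate`, `anisotropy`.
#' @export
sim_fp_displacement <- function(kd, config = fp_config(), cfg = sim_config(),
                                r_free = 0.05, r_bound = 0.25,
                                compound = "cmpd") {
  conc <- cfg$conc %||% (kd_to_ic50(kd, config) * 3^seq(5, -6))
  frac <- vapply(conc, function(it) {
    solve_competitive_equilibrium(config, it, kd)$EP / config$P_t
  }, numeric(1))
  r <- r_free + (r_bound - r_free) * frac
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(i = seq_along(conc),
                               replicate = seq_len(cfg$replicates))
    tibble::tibble(compound = compound, conc = conc[grid$i],
                   replicate = grid$replicate,
                   anisotropy = noisy(r[grid$i], cfg))
  })
}

#' Simulate covalent-inhibition FP time courses
#'
#' Per-concentration one-phase decays
#' `signal(t) = plateau + span * exp(-kobs t)` with
#' `kobs = k2 [I] / (ki + [I])`. The default design uses a 2-fold series
#' 5-320 uM and 9 time points over 24 h. `mechanism = "reequilibration"`
#' switches to an occupancy-coupled trace in which the unreacted protein
#' pool decays exponentially but the signal follows the re-equilibrated
#' bound-probe fraction of the remaining pool, which is not exactly
#' exponential; it exists for robustness testing of the exponential fit.
#'
#' @param ki,k2 True covalent parameters (molar; per hour).
#' @param cfg A [sim_config()].
#' @param span,plateau Signal decay amplitude and asymptote.
#' @param mechanism `"exponential"` (model-consistent, default) or
#'   `"reequilibration"`.
#' @param config [fp_config()] used only by the re-equilibration mechanism.
#' @param compound Compound label.
#' @return Tibble `compound`, `conc`, `time_h`, `replicate`, `signal`.
#' @export
sim_fp_timecourse <- function(ki, k2, cfg = sim_config(), span = 0.10,
                              plateau = 0.20,
                              mechanism = c("exponential", "reequilibration"),
                              config = fp_config(), compound = "cmpd") {
  mechanism <- match.arg(mechanism)
  conc <- cfg$conc %||% (5e-6 * 2^(0:6))
  times <- cfg$times %||% c(0, 0.5, 1, 2, 3, 4, 5, 8, 24)
  kobs <- k2 * conc / (ki + conc)
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(i = seq_along(conc), time_h = times,
                               replicate = seq_len(cfg$replicates))
    mu <- if (mechanism == "exponential") {
      plateau + span * exp(-kobs[grid$i] * grid$time_h)
    } else {
      frac0 <- solve_competitive_equilibrium(config, 0, 1)$EP / config$P_t
      e_frac <- exp(-kobs[grid$i] * grid$time_h)  # unreacted protein fraction
      bound <- vapply(e_frac, function(f) {
        cfgE <- fp_config(E_t = max(config$E_t * f, 1e-15),
                          P_t = config$P_t, KD_probe = config$KD_probe)
        solve_competitive_equilibrium(cfgE, 0, 1)$EP / config$P_t
      }, numeric(1))
      plateau + span * bound / frac0
    }
    tibble::tibble(compound = compound, conc = conc[grid$i],
                   time_h = grid$time_h, replicate = grid$replicate,
                   signal = noisy(mu, cfg))
  })
}

#' Simulate a BRET donor-saturation titration
#'
#' Wells spanning a relative-expression range whose background-corrected
#' ratios follow `BRETmax * x / (BRET50 + x)`, plus donor-only background
#' wells. Noise is applied to the acceptor-channel emission.
#'
#' @param bret_max,bret_50 True saturation parameters.
#' @param cfg A [sim_config()]; `cfg$conc` is not used, the expression grid
#'   is set by `x_max` and `n_points`.
#' @param x_max Largest relative expression (default 4 x `bret_50`).
#' @param n_points Number of titration points (default 12).
#' @param bg_ratio Donor-only raw 515/410 ratio (luciferase bleed-through).
#' @param rlu Donor-channel luminescence per well.
#' @param n_donor_only Donor-only background wells.
#' @return Tibble `well`, `condition`, `ad_ratio`, `rfu`, `em410`, `em515`,
#'   `replicate`.
#' @export
sim_bret_titration <- function(bret_max = 0.35, bret_50 = 1.0,
                               cfg = sim_config(), x_max = 4 * bret_50,
                               n_points = 12L, bg_ratio = 0.10, rlu = 1e5,
                               n_donor_only = 4L) {
  xs <- seq(x_max / n_points, x_max, length.out = n_points)
  withr::with_seed(cfg$seed, {
    grid <- tidyr::expand_grid(i = seq_len(n_points),
                               replicate = seq_len(cfg$replicates))
    ratio <- bret_max * xs[grid$i] / (bret_50 + xs[grid$i])
    da <- tibble::tibble(
      well = sprintf("DA%02d", seq_len(nrow(grid))),
      condition = "donor_acceptor", ad_ratio = xs[grid$i],
      rfu = xs[grid$i] * rlu, em410 = rlu,
      em515 = noisy(rlu * (ratio + bg_ratio), cfg),
      replicate = grid$replicate)
    donly <- tibble::tibble(
      well = sprintf("D%02d", seq_len(n_donor_only)),
      condition = "donor_only", ad_ratio = 0, rfu = 0, em410 = rlu,
      em515 = noisy(rep(rlu * bg_ratio, n_donor_only), cfg),
      replicate = seq_len(n_donor_only))
    dplyr::bind_rows(da, donly)
  })
}
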