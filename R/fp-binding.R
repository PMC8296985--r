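# Competitive fluorescence-polarization binding:
#   E + P <-> EP  (KD_probe)     E + I <-> EI  (Kd)
# A fluorescent probe peptide bound to calmodulin tumbles slowly and reads
# high anisotropy; displacement by an inhibitor lowers it. Because protein
# and probe are not in trace amounts, the displacement IC50 overestimates
# the inhibitor Kd and must be depletion-corrected.

#' Fluorescence-polarization assay configuration
#'
#' Totals and probe affinity of the competitive FP displacement assay.
#' Defaults correspond to 100 nM calmodulin, 10 nM fluorescein-labelled
#' PMCA peptide probe, and a probe dissociation constant of 6 nM.
#'
#' @param E_t Total protein concentration (molar).
#' @param P_t Total probe concentration (molar).
#' @param KD_probe Probe-protein dissociation constant (molar).
#' @return A list of class `fp_config`.
#' @export
fp_config <- function(E_t = 100e-9, P_t = 10e-9, KD_probe = 6e-9) {
  stopifnot(E_t > 0, P_t > 0, KD_probe > 0)
  structure(list(E_t = E_t, P_t = P_t, KD_probe = KD_probe),
            class = "fp_config")
}

#' Fluorescence anisotropy from polarized intensities
#'
#' `r = (I_par - G I_perp) / (I_par + 2 G I_perp)` with instrument G-factor
#' `G` (default 1).
#'
#' @param i_par,i_perp Parallel and perpendicular emission intensities.
#' @param g G-factor correcting detection-channel sensitivity.
#' @return Anisotropy (dimensionless), vectorized.
#' @export
anisotropy <- function(i_par, i_perp, g = 1) {
  stopifnot(all(i_par >= 0), all(i_perp >= 0))
  tot <- i_par + 2 * g * i_perp
  if (any(tot <= 0)) abort("Total intensity must be positive.")
  (i_par - g * i_perp) / tot
}

# bound probe concentration with no inhibitor: single-site quadratic
bound_probe_0 <- function(config) {
  b <- config$E_t + config$P_t + config$KD_probe
  (b - sqrt(b^2 - 4 * config$E_t * config$P_t)) / 2
}

#' Solve the three-species competitive binding equilibrium
#'
#' Unique equilibrium of E + P <-> EP and E + I <-> EI under total
#' concentrations `E_t`, `P_t`, `I_t`. Free protein solves the monotone
#' mass balance `E (1 + P_t/(KD_probe + E) + I_t/(kd + E)) = E_t`, bracketed
#' on `[0, E_t]` and found by 1-D root finding; all other species follow.
#'
#' @param config An [fp_config()].
#' @param I_t Total inhibitor concentration (molar), may be 0.
#' @param kd Inhibitor-protein dissociation constant (molar).
#' @param tol Root-finding tolerance on free protein.
#' @return One-row tibble: `E_free`, `P_free`, `I_free`, `EP`, `EI` (molar).
#' @export
solve_competitive_equilibrium <- function(config, I_t, kd, tol = 1e-18) {
  stopifnot(inherits(config, "fp_config"), I_t >= 0, kd > 0)
  f <- function(E) {
    E * (1 + config$P_t / (config$KD_probe + E) + I_t / (kd + E)) - config$E_t
  }
  fp <- function(E) {
    1 + config$P_t * config$KD_probe / (config$KD_probe + E)^2 +
      I_t * kd / (kd + E)^2
  }
  E <- uniroot(f, c(0, config$E_t), tol = tol)$root
  # Newton polish to machine precision (stiff when totals >> either KD)
  for (i in 1:5) {
    step <- f(E) / fp(E)
    E <- min(max(E - step, 0), config$E_t)
    if (abs(step) <= .Machine$double.eps * E) break
  }
  P <- config$P_t * config$KD_probe / (config$KD_probe + E)
  I <- I_t * kd / (kd + E)
  tibble::tibble(E_free = E, P_free = P, I_free = I,
                 EP = E * P / config$KD_probe, EI = E * I / kd)
}

#' Fit a displacement IC50 from anisotropy vs inhibitor concentration
#'
#' Four-parameter log-logistic fit on the anisotropy scale (rising or
#' falling curves both allowed); the IC50 is the concentration at the
#' midpoint of the anisotropy transition, i.e. 50% probe displacement.
#'
#' @param data Data frame of the titration.
#' @param conc,response Columns with inhibitor concentration (molar) and
#'   anisotropy.
#' @return A `logistic4_fit` (see [fit_logistic4()]); `$ic50` in molar.
#' @export
fit_displacement_ic50 <- function(data, conc = conc, response = anisotropy) {
  fit_logistic4(data, conc = {{ conc }}, response = {{ response }},
                bounds = "free")
}

#' Convert a displacement IC50 into an inhibitor Kd
#'
#' Depletion-corrected competitive-binding conversion. From the assay
#' totals and probe KD it computes the inhibitor-free bound probe
#' `EP_0` (single-site quadratic), then at 50% displacement:
#' `EP_50 = EP_0/2`, free probe `P_50 = P_t - EP_50`, free protein
#' `E_50 = KD_probe EP_50 / P_50`, inhibitor complex
#' `EI_50 = E_t - E_50 - EP_50`, free inhibitor `I_50 = IC50 - EI_50`,
#' and zero-displacement free protein `E_0 = E_t - EP_0`. Then
#'
#'   `Kd = I_50 / (1 + P_50/KD_probe + E_0/KD_probe)`
#'
#' `I_50 <= 0` (IC50 smaller than the depleted complex) signals tight
#' binding: the Kd is then an upper bound and is flagged.
#'
#' @param ic50 Displacement IC50 (molar).
#' @param config An [fp_config()].
#' @return One-row tibble with `ic50`, `kd`, the correction terms `I_50`,
#'   `P_50`, `E_0`, `EI_50`, `EP_0`, and `tight_binding`.
#' @export
ic50_to_kd <- function(ic50, config) {
  stopifnot(ic50 > 0, inherits(config, "fp_config"))
  EP0 <- bound_probe_0(config)
  EP50 <- EP0 / 2
  P50 <- config$P_t - EP50
  E50 <- config$KD_probe * EP50 / P50
  EI50 <- config$E_t - E50 - EP50
  I50 <- ic50 - EI50
  E0 <- config$E_t - EP0
  tight <- I50 <= 0
  if (tight) {
    warn("IC50 below the depleted-complex concentration: tight-binding regime; Kd is an upper bound.")
    I50 <- ic50 * .Machine$double.eps^0.5
  }
  kd <- I50 / (1 + P50 / config$KD_probe + E0 / config$KD_probe)
  tibble::tibble(ic50 = ic50, kd = kd, I_50 = I50, P_50 = P50, E_0 = E0,
                 EI_50 = EI50, EP_0 = EP0, tight_binding = tight)
}

#' Expected displacement IC50 for a given inhibitor Kd
#'
#' Exact inverse of [ic50_to_kd()] under the same depletion correction:
#' `IC50 = Kd (1 + P_50/KD_probe + E_0/KD_probe) + EI_50`. Useful for
#' designing a titration that brackets the transition midpoint.
#'
#' @param kd Inhibitor dissociation constant (molar).
#' @param config An [fp_config()].
#' @return Expected IC50 (molar), vectorized over `kd`.
#' @export
kd_to_ic50 <- function(kd, config) {
  stopifnot(all(kd > 0), inherits(config, "fp_config"))
  EP0 <- bound_probe_0(config)
  EP50 <- EP0 / 2
  P50 <- config$P_t - EP50
  E50 <- config$KD_probe * EP50 / P50
  EI50 <- config$E_t - E50 - EP50
  E0 <- config$E_t - EP0
  kd * (1 + P50 / config$KD_probe + E0 / config$KD_probe) + EI50
}
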