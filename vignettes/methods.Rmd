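---
title: "Methods: models, estimators, and numerical choices in covscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and numerical choices in covscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covscreen)
library(dplyr)
```

This vignette documents the statistical models behind each module, the
default parameters and why they were chosen, what the synthetic-data
generators do and do not emulate, and the numerical decisions that a reader
reproducing the analysis should know about.

## Plate normalization

Raw plate-reader signals are normalized against on-plate controls. For
viability,

$$\text{viability \%} = 100\,\frac{s - \bar{k}}{\bar{v} - \bar{k}},$$

where $\bar{v}$ and $\bar{k}$ are the mean vehicle and kill-control signals.
When a plate carries no kill controls, the assay background is taken as zero
signal and negative values are floored at 0. Percent inhibition is the
involution $100 - \text{viability}$.

**Toxicity anchoring.** Toxicity reads can arrive in two conventions: plates
with an explicit kill control (anchor: vehicle = 0 %, kill = 100 %) and
plates without one, where the only defensible ceiling is the plate's own
maximum signal. `normalize_toxicity()` supports both and records which anchor
was used; this is a package decision, not something the raw files disambiguate.

## Four-parameter logistic dose–response

The response at log10 molar concentration $x$ is

$$y(x) = b + \frac{t - b}{1 + 10^{\,h\,(m - x)}},$$

with bottom $b$, top $t$, Hill slope $h$, and log10 midpoint $m$. A negative
$h$ gives a falling curve whose *top* sits at low dose, so $t \ge b$ in both
orientations; `fit_logistic4()` canonicalizes fits accordingly and tries both
orientations from multiple midpoint starts (the quartiles of the tested
range plus one start outside each end, which rescues near-saturated curves
whose midpoint lies off-grid). Fitting uses bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`) with default convergence tolerances — tightening
`ftol`/`ptol` to $10^{-12}$ was found to make *exact* starting values error
out with singular-gradient failures, leaving only worse local optima.

Default bounds ($b \in [-10, 50]$, $t \in [0, 120]$, $|h| \in [0.2, 10]$,
$m$ within the tested range $\pm 2$ decades) encode that normalized percent
scales can mildly overshoot their anchors but not arbitrarily. Passing
`bounds = "free"` disables them, which the FP module uses because anisotropy
curves live on a different scale.

## Area under the curve and drug sensitivity scores

The AUC of the logistic over $[x_\ell, x_u]$ has the closed form

$$\mathrm{AUC} = b\,(x_u - x_\ell) + \frac{t - b}{k}\left[\,\mathrm{softplus}(k(x_u - m)) - \mathrm{softplus}(k(x_\ell - m))\,\right],\quad k = h \ln 10,$$

with a constant-curve branch when $|k| < 10^{-14}$. The test suite checks
this against adaptive quadrature to $10^{-6}$ relative over 1000 random
parameter draws.

The drug sensitivity scores integrate only response above an activity
threshold $t_\%$ (default 10 %):

$$\mathrm{DSS1} = \frac{\mathrm{AUC} - t_\%\,(x_2 - x_1)}{(100 - t_\%)(C_{\max} - C_{\min})},$$

where $x_1$ is the log-concentration at which the fitted curve crosses
$t_\%$ (clamped into the window) and $x_2 = C_{\max}$. DSS2 divides by
$\log_{10} a$ with $a$ the top asymptote clamped to $[t_\%, 100]$; DSS3
multiplies DSS2 by $(x_2 - x_1)/(C_{\max} - C_{\min})$. Raw scores lie in
$[0, 1]$ and are reported ×100, so complete inhibition over the whole window
scores DSS1 = 100 and DSS2 = DSS3 = 50 — this ×100 convention is a package
choice and the analytic anchor the acceptance suite verifies. Curves whose
fitted maximum never exceeds $t_\%$, and curves that do not actually fall as
concentration rises (judged by comparing $y(C_{\max})$ against
$y(C_{\min})$, not by the sign of the Hill slope, which is unreliable for
near-flat fits), score 0. An external asymptote `a` can be supplied for
assays where the achievable ceiling comes from a reference compound rather
than the fit (the BRET module does this).

## Competitive fluorescence-polarization binding

Target $E$, fluorescent probe $P$ (dissociation constant $K_P$), and
inhibitor $I$ (dissociation constant $K_d$) form the two-ligand competitive
equilibrium. Free target concentration solves

$$E\left(1 + \frac{P_t}{K_P + E} + \frac{I_t}{K_d + E}\right) = E_t,$$

found by `uniroot` on $[0, E_t]$ followed by a few Newton steps (the
analytic derivative is available), which pushes the mass-balance residual
from roughly $10^{-5}$ relative down to machine precision for stiff
parameter ratios.

Anisotropy is modeled as a linear mix of free and bound probe:
$r = r_f + (r_b - r_f)\,[EP]/P_t$; with measured parallel/perpendicular
intensities, $r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G I_\perp)$.
The **G-factor defaults to 1.0** — instrument calibration is site-specific
and the package cannot know it, so the default is the identity correction
and callers supply their own.

The IC50→Kd conversion accounts for probe and target depletion exactly at
the half-displacement point: from the inhibitor-free bound probe $[EP]_0$
(a quadratic), the half-point species are $[EP]_{50} = [EP]_0/2$,
$P_{50} = P_t - [EP]_{50}$, $E_{50} = K_P [EP]_{50}/P_{50}$,
$[EI]_{50} = E_t - E_{50} - [EP]_{50}$, $I_{50} = \mathrm{IC50} - [EI]_{50}$,
and

$$K_d = \frac{I_{50}}{1 + P_{50}/K_P + E_0/K_P}.$$

This is algebraically exact when the fitted IC50 equals the true
half-displacement concentration (verified numerically to $10^{-8}$
relative). The default assay configuration (`fp_config()`: 100 nM target,
10 nM probe, 6 nM probe KD) reflects a standard competitive FP setup where
the probe is sub-stoichiometric to the target. In the tight-binding regime
($K_d$ approaching the nanomolar target concentration) the conversion
degrades — at $K_d$ = 10 nM the round-trip error reaches ~7 % — which is why
supported affinities are stated as 0.1–100 µM; Morrison-type tight-binding
analysis is out of scope.

The default displacement series is adaptive: twelve 3-fold dilutions
centered near the *predicted* IC50 (`kd_to_ic50()`, the exact inverse of the
conversion above). A fixed series topping out at 300 µM cannot bracket the
midpoint of a 39 µM binder (expected IC50 ≈ 663 µM); centering the series is
how a competent assay would be designed, not a tuning of the estimator.

## Covalent kinetics

Displacement time courses follow
$y(t) = \text{plateau} + \text{span}\,e^{-k_{\mathrm{obs}} t}$, fitted per
concentration with a half-life-based start and $k_{\mathrm{obs}} \ge 0$. The
**plateau is deliberately unconstrained**: covalent engagement can drive
bound probe essentially to zero or stall partway, and pinning the plateau
would bias $k_{\mathrm{obs}}$. A signal range below $10^{-12}$ of scale is
declared flat ($k_{\mathrm{obs}} = 0$) rather than fitted.

The concentration dependence
$k_{\mathrm{obs}} = k_2 [I]/(K_i + [I])$ is fitted with inverse-variance
weights from the per-concentration standard errors when available. When the
hyperbola is unresolved ($\hat{K}_i$ beyond 50× the top tested concentration,
or non-convergence) the pipeline falls back to the linear regime and reports
only the slope $k_2/K_i$ — the quantity that remains identifiable.

The second-order efficiency $k_2/K_i$ is tabulated with a magnitude-dependent
rule: two significant figures at or above $10^4$ M⁻¹h⁻¹, one below
(`round_second_order()`), matching common reporting practice for these rates.

## BRET donor-saturation titrations

The background-corrected ratio is
$(515/410)_{\text{sample}} - (515/410)_{\text{donor only}}$; it is invariant
to common scaling of a well's channels and exactly zero when sample and
donor-only raw ratios coincide. Relative acceptor expression is acceptor
fluorescence over donor luminescence. Saturation follows
$y = \mathrm{BRET}_{\max}\, x/(\mathrm{BRET}_{50} + x)$; a titration that
never bends ($\hat{\mathrm{BRET}}_{50}$ beyond 50× the tested expression
range) is flagged linear with only a slope reported.

**"Most linear" assay window.** Dose–response BRET experiments want the
plasmid ratio whose expression sits in the quasi-linear part of the
saturation curve — high enough for signal, low enough that engagement
changes translate proportionally into ratio changes. The package
operationalizes this as the tested acceptor/donor ratio whose mean relative
expression is closest to $\mathrm{BRET}_{50}/2$, with ties broken toward the
lower plasmid ratio (less perturbation); if every candidate sits beyond
3× BRET50 the function warns and returns the lowest-expression ratio.

Percent inhibition of engagement is anchored at the vehicle ratio (0 %),
and the achievable ceiling can be taken from a reference compound's
asymptote, which then feeds DSS2 as the external `a` described above.

## Composite prioritization score

$$\text{score} = \frac{\mathrm{DSS3}_{\text{target}}^2}{\mathrm{DSS3}_{\text{off-target}}} \cdot \frac{\mathrm{Tox}_{\text{off-target}}}{\mathrm{Tox}_{\text{target}}} \cdot \frac{1}{K_d\,(\mu M)}.$$

The score is quadratic in target potency, inversely linear in off-target
potency, target toxicity, and $K_d$ — halving $K_d$ exactly doubles the
score, and equal DSS/toxicity pairs at $K_d = 1\,\mu M$ collapse to the
target DSS. Rows with a non-positive denominator are excluded with a recorded
reason rather than producing infinities. Ranking is fully deterministic:
descending score, then lower $K_d$, then compound identifier.

## Synthetic data: realism and limits

All generators run under `withr::with_seed`, so they are bit-reproducible
and leave the caller's RNG stream untouched. Noise is multiplicative
(coefficient of variation `cv`, default 2 %) with optional additive Gaussian
noise, applied to *raw* signals before normalization — so normalized noise
correctly inflates near the kill control, as on real plates.

What they emulate: control-well structure, replicate structure, the exact
equilibrium model for displacement curves (not a logistic approximation),
and single-exponential or probe re-equilibration time-course shapes. What
they do not: plate-position effects, edge evaporation, compound
fluorescence interference, heteroscedasticity beyond the cv model, or
instrument drift. Conclusions about robustness to those artifacts cannot be
drawn from these simulations.

Default problem sizes — 10-point dose–response from 0.6–40 µM, 12-point
3-fold displacement series, 7 time-course concentrations from 5–320 µM
(2-fold) over 9 time points spanning 24 h, 12-point BRET titrations — are
the package's own choices of realistic assay designs, sized so that every
parameter of the corresponding model is identifiable from one simulated
experiment at the default noise level.

## Verification strategy

Every estimator is checked against an independent oracle in the test suite:
closed-form AUC against adaptive quadrature, logistic and saturation fits
against brute-force grid searches, the equilibrium solver against a refined
grid scan of the mass-balance objective, and DSS against a direct
implementation of its printed formulas using numeric root-finding and
quadrature. Recovery tolerances (covalent parameters within 10 % median at
1 % noise; BRETmax within 5 % median at 2 % noise; Kd round trips within
2 % noiseless) are stated in the acceptance tests and were not adjusted to
fit observed performance.
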