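# covscreen

Tidyverse-native analysis of covalent-inhibitor screening campaigns against
calmodulin-family targets. The package covers the full quantitative path of a
typical campaign:

1. **Plate normalization** — raw viability/toxicity plate reads are normalized
   against vehicle and kill-control wells into percent viability, percent
   inhibition, or percent toxicity (`read_plate_table()`,
   `normalize_viability()`, `normalize_toxicity()`, `percent_inhibition()`).
2. **Dose–response** — four-parameter logistic fits in log10 concentration
   (`fit_logistic4()`), a closed-form area under the inhibition curve
   (`auc_logistic4()`), and the normalized drug sensitivity scores DSS1–DSS3
   (`dss()`), which integrate the fitted curve above a 10 % activity threshold
   and rescale by the tested window so that complete inhibition scores
   DSS1 = 100 and DSS2 = DSS3 = 50.
3. **Fluorescence-polarization binding** — the competitive three-species
   equilibrium (target + probe + inhibitor) is solved exactly
   (`solve_competitive_equilibrium()`), displacement curves are fitted for
   IC50 (`fit_displacement_ic50()`), and IC50 is converted to a true
   dissociation constant with a correction that accounts for probe and target
   depletion (`ic50_to_kd()`, inverse `kd_to_ic50()`).
4. **Covalent kinetics** — time courses of probe displacement are fitted per
   concentration for an observed rate *k*obs (`fit_kobs()`), the hyperbolic
   dependence *k*obs = *k*2·[I]/(*K*i + [I]) yields *K*i and *k*2
   (`fit_ki_k2()`, pipeline `covalent_kinetics()`), and the second-order
   efficiency *k*2/*K*i is reported at tabulation precision
   (`second_order_rate()`, `round_second_order()`).
5. **BRET target engagement** — background-corrected BRET ratios
   (`bret_ratio()`), acceptor/donor relative expression
   (`relative_expression()`), saturation fits for BRETmax and BRET50
   (`fit_saturation()`), selection of the plasmid ratio sitting in the
   quasi-linear sub-saturation window (`select_assay_ad_ratio()`), and percent
   inhibition of engagement anchored to a reference compound
   (`bret_inhibition()`).
6. **Compound prioritization** — a composite selectivity score
   DSS²target/DSSoff-target × Toxoff-target/Toxtarget × 1/Kd(µM)
   (`composite_score()`) with deterministic ranking and per-series selection
   (`rank_compounds()`).
7. **Synthetic data** — seeded, bit-reproducible generators for every assay
   (`sim_dose_response()`, `sim_fp_displacement()`, `sim_fp_timecourse()`,
   `sim_bret_titration()`), used throughout the test suite as ground truth.

All analysis functions are data-frame-first: they accept tibbles, return
tibbles or small fit objects, and every fit class has `tidy()`, `glance()`,
and `autoplot()` methods.

## Worked example

Simulate a 3-replicate dose–response plate for a compound with true IC50
2.5 µM (log10 −5.6) and 92 % maximal inhibition, normalize it, fit, and
score:

```r
library(covscreen)
library(dplyr)

plate <- sim_dose_response(bottom = 0, top = 92, hill = 1.1,
                           log10_ic50 = -5.6,
                           cfg = sim_config(seed = 7, cv = 0.02, replicates = 3))
inh <- percent_inhibition(normalize_viability(plate)) |>
  filter(compound == "cmpd")
fit <- fit_logistic4(inh, conc = conc, response = value)
fit
#> <logistic4_fit> bottom 2.93, top 92.1, hill 1.13, logIC50 -5.56 (IC50 2.78e-06 M), n = 10

tidy(fit)
#> # A tibble: 4 × 3
#>   term      estimate std.error
#>   <chr>        <dbl>     <dbl>
#> 1 bottom        2.93    3.42
#> 2 top          92.1     1.54
#> 3 hill          1.13    0.0866
#> 4 log10_mid    -5.56    0.0288

dss(fit, t = 10, cmin = log10(min(inh$conc)), cmax = log10(max(inh$conc)))
#> # A tibble: 1 × 13
#>   compound  dss1  dss2  dss3   auc     t     a    x1    x2  cmin  cmax     ic50
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>    <dbl>
#> 1 <NA>      52.6  26.8  26.8  105.    10  92.1 -6.22 -4.40 -6.22 -4.40  2.78e-6
```

Binding affinity from a fluorescence-polarization displacement curve
(100 nM target, 10 nM probe, 6 nM probe KD), with the depletion-corrected
IC50→Kd conversion recovering the generating Kd of 0.87 µM:

```r
cam <- fp_config()   # E_t = 100 nM, P_t = 10 nM, KD_probe = 6 nM
d <- sim_fp_displacement(0.87e-6, config = cam,
                         cfg = sim_config(seed = 7, cv = 0.01, replicates = 3))
ic <- fit_displacement_ic50(d)
kd <- ic50_to_kd(ic$ic50, cam)
sprintf("IC50 = %.1f uM -> Kd = %.2f uM", ic$ic50 * 1e6, kd$kd * 1e6)
#> [1] "IC50 = 15.2 uM -> Kd = 0.89 uM"
```

Covalent kinetics from a simulated time-course panel (7 concentrations, 9
time points over 24 h, 1 % noise; truth *K*i = 79 µM, *k*2 = 1.09 h⁻¹):

```r
tc <- sim_fp_timecourse(79e-6, 1.09,
                        cfg = sim_config(seed = 7, cv = 0.01, replicates = 1))
ck <- covalent_kinetics(tc)
ck
#> <covalent_fit> Ki 8.3e-05 M, k2 1.13 /h, k2/Ki 1.36e+04 /M/h (n = 7)

round_second_order(second_order_rate(ck$k2, ck$ki))
#> [1] 14000
```

## License

MIT.
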