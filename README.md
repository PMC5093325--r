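# filakin

Stochastic growth kinetics of two-ended supramolecular filaments.

Short aromatic peptides such as diphenylalanine (FF) self-assemble into
crystalline nanotubes whose elongation and shortening can be watched one
filament at a time when the assembly is confined in a microfluidic channel
and the monomer concentration is programmed by co-flowing two solutions.
`filakin` is an R package for scientists analysing (or simulating) such
experiments. It provides:

* an **exact Gillespie simulator** of a two-ended filament with independent
  attachment/detachment/capping kinetics per terminus, in an *open bath*
  (continuous flow, constant concentration) or a *closed pool* (finite
  reservoir relaxing to equilibrium);
* **growth-law estimation**: the net growth rate of a filament is linear in
  the local monomer concentration *c*,

  *R*(*c*) = *k*<sub>on</sub> · *c* − *k*<sub>off</sub>,

  with critical concentration *c*<sub>s</sub> = *k*<sub>off</sub>/*k*<sub>on</sub>
  where assembly and disassembly balance. `fit_growth_law()` estimates the
  parameters from (concentration, rate) points by (weighted) OLS, with
  broom-style `tidy()`/`glance()` accessors and a delta-method confidence
  interval for *c*<sub>s</sub>;
* a **per-terminus directionality classifier** (unidirectional vs
  bidirectional vs stalled growth) built on per-end activity *z* tests;
* **co-flow mixing arithmetic** and mg/ml ↔ mM conversions for programming
  the in-channel concentration;
* a **synthetic-data generator** emulating the microscopy protocol:
  frame-sampled terminus positions, each reported as the average of five
  replicate reads, ten tubes per concentration condition.

Everything is tidyverse-shaped: functions take data frames first, return
tibbles, and results have `autoplot()` methods.

## Worked example

Kinetics of FF nanotubes in water, using the fitted constants
*k*<sub>on</sub> = 3.36 µm·min⁻¹·mM⁻¹ and *k*<sub>off</sub> = 7.4 µm·min⁻¹:

```r
library(filakin)

ff <- kinetic_params(k_on = 3.36, k_off = 7.4)
net_growth_rate(3.20, ff)                        # 3.352  µm/min: supercritical growth
net_growth_rate(1.60, ff)                        # -2.024 µm/min: subcritical shortening
round_half_up(critical_concentration(ff), 1)     # 2.2 mM

# programming the channel: two stocks merged at given flow rates
mixing_spec(conc = c(3.20, 1.60), flow_ul_h = c(2.2, 1.7), unit = "mM") |>
  mixed_concentration()
#>    conc unit  total_flow_ul_h
#> 1  2.50 mM                3.9
```

The full synthetic pipeline — simulate ten filaments at each of five
concentrations, observe them through the noisy measurement model, estimate
per-terminus rates, fit the growth law, classify directionality:

```r
report <- run_recovery(experiment_design(seed = 1))
report
#> Per-condition net growth rates (um/min):
#>  conc_mM rate_um_min      se n_tubes weight
#>      1.6     -2.0294 0.03839      10  678.3
#>      2.4      0.6592 0.03778      10  700.7
#>      2.8      1.9774 0.04426      10  510.4
#>      3.2      3.3105 0.05076      10  388.2
#>      3.6      4.7353 0.04445      10  506.2
#>
#> <growth_law_fit> R = k_on * c - k_off
#>   k_on  = 3.368 +/- 0.0206 um/min/mM
#>   k_off = 7.429 +/- 0.0555 um/min
#>   c_s   = 2.205 mM
#>   r^2 = 0.9999 on 5 points
#>
#> Critical concentration: 2.205 mM (95% CI 2.190-2.221)
#>
#> Directionality tally (alpha = 0.01 ):
#>           label n_tubes
#>  unidirectional      50
```

The generating truth (3.36, 7.4) is recovered within the fit's confidence
intervals, and every tube of the strongly asymmetric FF preset is called
unidirectional — growth and shortening confined to one terminus. The
symmetric cycloFF preset (`cycloff_filament()`) yields bidirectional calls
instead. `autoplot(report)` draws the rate-versus-concentration fit with
its critical-concentration intercept; see the vignette
(`vignettes/filament-kinetics.Rmd`) for the model, the measurement-noise
assumptions, and the design decisions.

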